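#' Read and write trajectory tables
#'
#' Trajectories travel as CSV with the header
#' `particle_id,frame,time_s,position_um,intensity_au` (intensity optional
#' on read). `write_trajectories()` writes exactly this dialect.
#'
#' @param path CSV file path.
#' @param trajs A trajectory tibble.
#' @return `read_trajectories()` returns a `trajectory_set` tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
read_trajectories <- function(path) {
  res <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("particle_id", "frame", "time_s", "position_um")
  if (!all(need %in% names(res))) {
    abort(paste("trajectory CSV must have columns:",
                paste(need, collapse = ", ")))
  }
  if (!"intensity_au" %in% names(res)) res$intensity_au <- NA_real_
  res <- res %>%
    select("particle_id", "frame", "time_s", "position_um", "intensity_au") %>%
    arrange(.data$particle_id, .data$frame)
  class(res) <- c("trajectory_set", class(res))
  res
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajs, path) {
  cols <- c("particle_id", "frame", "time_s", "position_um", "intensity_au")
  readr::write_csv(trajs[, intersect(cols, names(trajs))], path)
  invisible(path)
}

#' Write per-track diffusion estimates and a summary
#'
#' Writes the per-track table from [estimate_diffusion()] (optionally
#' joined with [run_lengths()]) as CSV, and, if `summary_path` is given, a
#' JSON summary with the median D, median run length and track count.
#'
#' @param estimates Tibble from [estimate_diffusion()].
#' @param path Output CSV path.
#' @param runs Optional tibble from [run_lengths()].
#' @param summary_path Optional JSON path for the medians.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, runs = NULL,
                            summary_path = NULL) {
  out <- estimates
  if (!is.null(runs)) {
    out <- dplyr::left_join(out, runs, by = "particle_id")
  }
  readr::write_csv(out, path)
  if (!is.null(summary_path)) {
    s <- list(n_tracks = nrow(estimates),
              median_D_um2_per_s = median(estimates$D_um2_per_s))
    if (!is.null(runs)) s$median_run_length_um <- median(runs$run_length_um)
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
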
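#' Estimate flow drift velocity from a trajectory set
#'
#' The common drift of DNA-bound particles under flow, estimated as the
#' ratio of summed net displacements to summed elapsed times over all
#' trajectories, `v = sum_j (x_final - x_initial) / sum_j (t_final -
#' t_initial)`, signed along the flow direction. Diffusive displacements
#' average out, so the estimator needs no per-track fitting.
#'
#' @param trajs A `trajectory_set` tibble (>= 1 track with duration > 0).
#' @return An object of class `drift_estimate` with `v_um_per_s`,
#'   `n_trajectories` and `total_time_s`.
#' @examples
#' cfg <- sim_config(D = 0.026, drift_v = 0.127, n_particles = 50,
#'                   mean_dwell_s = 5, step_rule = "ignore", seed = 11)
#' sub <- dna_substrate(anchoring = "single_tethered")
#' estimate_drift(simulate_trajectories(cfg, sub, flow_on = TRUE))
#' @export
estimate_drift <- function(trajs) {
  ends <- trajs %>%
    group_by(.data$particle_id) %>%
    summarise(dx = dplyr::last(.data$position_um) -
                dplyr::first(.data$position_um),
              dt = dplyr::last(.data$time_s) - dplyr::first(.data$time_s),
              .groups = "drop")
  total_t <- sum(ends$dt)
  if (!nrow(ends) || total_t <= 0) {
    abort("drift undefined: total trajectory duration is zero")
  }
  structure(list(v_um_per_s = sum(ends$dx) / total_t,
                 n_trajectories = nrow(ends),
                 total_time_s = total_t),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("<drift_estimate> v = %.4g um/s (%d tracks, %.1f s total)\n",
              x$v_um_per_s, x$n_trajectories, x$total_time_s))
  invisible(x)
}

#' Remove flow drift from trajectories
#'
#' Subtracts the linear drift `v * (t - t0)` from every track, with `t0`
#' each track's first time point; the time base is unchanged. `v` may be a
#' number (um/s) or an [estimate_drift()] result.
#'
#' @param trajs A `trajectory_set` tibble.
#' @param v Drift velocity, um/s, or a `drift_estimate`.
#' @return The trajectory tibble with corrected `position_um`.
#' @export
correct_drift <- function(trajs, v) {
  if (inherits(v, "drift_estimate")) v <- v$v_um_per_s
  check_number(v, "v")
  out <- trajs %>%
    group_by(.data$particle_id) %>%
    mutate(position_um = .data$position_um -
             v * (.data$time_s - dplyr::first(.data$time_s))) %>%
    ungroup()
  attr(out, "substrate") <- attr(trajs, "substrate")
  class(out) <- class(trajs)
  out
}

#' Run lengths of particles along DNA
#'
#' The net travel distance of each particle: absolute displacement from its
#' first bound position to its final position (tip arrival or unbinding).
#' On nucleosome-loaded DNA, reflecting barriers cap the achievable run
#' length, so the run-length distribution is stochastically smaller than on
#' bare DNA.
#'
#' @param trajs A `trajectory_set` tibble (non-empty).
#' @param substrate Optional [dna_substrate()]; defaults to the substrate
#'   attached to `trajs`. Positions must lie in substrate coordinates.
#' @return A tibble with `particle_id`, `run_length_um`, `duration_s`;
#'   the median run length and track count are stored in attributes
#'   `"median_um"` and `"n"`.
#' @export
run_lengths <- function(trajs, substrate = attr(trajs, "substrate")) {
  if (is.null(trajs) || !nrow(trajs)) abort("empty trajectory set")
  res <- trajs %>%
    group_by(.data$particle_id) %>%
    summarise(run_length_um = abs(dplyr::last(.data$position_um) -
                                    dplyr::first(.data$position_um)),
              duration_s = dplyr::last(.data$time_s) -
                dplyr::first(.data$time_s),
              .groups = "drop")
  attr(res, "median_um") <- median(res$run_length_um)
  attr(res, "n") <- nrow(res)
  res
}
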
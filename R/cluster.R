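#' Single-fluorophore unit intensity
#'
#' Robust calibration of the single-molecule intensity that converts cluster
#' intensities to molecule counts. Returns the median with its MAD; a
#' bimodality check (1- vs 2-component Gaussian mixture BIC) warns when the
#' input looks like a mixture of true singles and undetected multiples,
#' which would inflate the unit.
#'
#' @param single_molecule_intensities Numeric intensities of isolated single
#'   molecules (>= 20 values).
#' @return An object of class `unit_intensity`: list with `unit_au`
#'   (median), `mad_au`, `n`, `bimodal`.
#' @examples
#' u <- unit_intensity(rnorm(200, 100, 30))
#' u$unit_au
#' @export
unit_intensity <- function(single_molecule_intensities) {
  x <- single_molecule_intensities[is.finite(single_molecule_intensities)]
  if (length(x) < 20) abort("need at least 20 single-molecule intensities")
  bimodal <- FALSE
  if (sd(x) > 0) {
    fit <- suppressWarnings(
      mclust::mclustBIC(x, G = 1:2, modelNames = "V", verbose = FALSE))
    bics <- apply(fit, 1, max, na.rm = TRUE)
    # BIC in mclust is to-be-maximized; require a clear 2-component win
    bimodal <- is.finite(bics[2]) && bics[2] > bics[1] + 10
  }
  if (bimodal) {
    warn(paste0("single-molecule intensity distribution looks bimodal ",
                "(mixture check); unit intensity may be inflated by ",
                "undetected multi-molecule particles"))
  }
  structure(list(unit_au = median(x), mad_au = mad(x), n = length(x),
                 bimodal = bimodal),
            class = "unit_intensity")
}

#' @export
print.unit_intensity <- function(x, ...) {
  cat(sprintf("<unit_intensity> %.4g +/- %.4g a.u. (median +/- MAD, n=%d)%s\n",
              x$unit_au, x$mad_au, x$n,
              if (x$bimodal) " [bimodal warning]" else ""))
  invisible(x)
}

#' Convert cluster intensities to molecule counts
#'
#' `n = round(intensity / unit)`, floored at one molecule. Counts are scale
#' invariant: multiplying intensities and unit by the same factor leaves
#' them unchanged. Non-positive intensities are skipped with a warning.
#'
#' @param intensities Cluster intensities, a.u.
#' @param unit Unit intensity (a number or a [unit_intensity()] object).
#' @return Integer molecule counts (one per retained intensity).
#' @examples
#' cluster_sizes(c(100, 820, 250), 100)
#' @export
cluster_sizes <- function(intensities, unit) {
  if (inherits(unit, "unit_intensity")) unit <- unit$unit_au
  check_number(unit, "unit", lower = 1e-300)
  bad <- !is.finite(intensities) | intensities <= 0
  if (any(bad)) {
    warn(sprintf("%d non-positive intensity record(s) skipped", sum(bad)))
    intensities <- intensities[!bad]
  }
  pmax(1L, as.integer(round(intensities / unit)))
}

#' Cluster growth rate and size-dependent mobility
#'
#' From time-resolved cluster records, estimates each cluster's molecule
#' addition rate (the least-squares slope of n over time), tests whether
#' the addition rate depends on cluster size by Spearman rank correlation
#' of rate against initial size, and summarizes mobility as the median
#' fitted diffusion coefficient per size bin. Clusters whose fitted D
#' falls below `immobile_threshold` are flagged immobile.
#'
#' @param records A tibble of cluster records with columns `cluster_id`,
#'   `time_s`, `position_um`, `n_molecules` (>= 2 time points per cluster),
#'   e.g. from [simulate_cluster_growth()].
#' @param immobile_threshold D below which a cluster is called immobile,
#'   um^2/s. Default 1e-3, an order of magnitude below typical
#'   single-molecule mobility.
#' @return A list of class `cluster_growth` with elements
#'   `per_cluster` (tibble: `cluster_id`, `addition_rate_per_s`,
#'   `initial_size`, `mean_size`, `D_um2_per_s`, `immobile`),
#'   `rate_vs_size` (Spearman `rho` and `p_value`), and
#'   `D_vs_size` (tibble: `size`, `median_D_um2_per_s`, `n`).
#' @export
growth_and_mobility <- function(records, immobile_threshold = 1e-3) {
  need <- c("cluster_id", "time_s", "position_um", "n_molecules")
  if (!all(need %in% names(records))) {
    abort(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  per <- records %>%
    group_by(.data$cluster_id) %>%
    filter(dplyr::n() >= 2) %>%
    summarise(
      addition_rate_per_s =
        unname(coef(lm(n_molecules ~ time_s,
                       data = dplyr::pick(dplyr::everything())))[2]),
      initial_size = dplyr::first(.data$n_molecules),
      mean_size = mean(.data$n_molecules),
      .groups = "drop")
  if (!nrow(per)) abort("no cluster has >= 2 time points")
  d_est <- map_dbl(per$cluster_id, function(id) {
    tr <- records[records$cluster_id == id, ]
    if (nrow(tr) < 13) return(NA_real_)
    fit <- fit_diffusion(compute_msd(
      tibble(time_s = tr$time_s, position_um = tr$position_um),
      max_lags = 20))
    fit$D_um2_per_s
  })
  per$D_um2_per_s <- d_est
  per$immobile <- !is.na(d_est) & d_est < immobile_threshold
  rvs <- if (nrow(per) >= 4 && sd(per$initial_size) > 0) {
    ct <- suppressWarnings(
      cor.test(per$addition_rate_per_s, per$initial_size,
               method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  dvs <- per %>%
    filter(!is.na(.data$D_um2_per_s)) %>%
    mutate(size = round(.data$mean_size)) %>%
    group_by(.data$size) %>%
    summarise(median_D_um2_per_s = median(.data$D_um2_per_s),
              n = dplyr::n(), .groups = "drop")
  structure(list(per_cluster = per, rate_vs_size = rvs, D_vs_size = dvs),
            class = "cluster_growth")
}

#' @export
print.cluster_growth <- function(x, ...) {
  cat(sprintf(
    "<cluster_growth> %d clusters; rate-vs-size Spearman rho = %.3f (p = %.3g)\n",
    nrow(x$per_cluster), x$rate_vs_size$rho, x$rate_vs_size$p_value))
  invisible(x)
}

#' Colocalization fraction between two position sets
#'
#' Fraction of positions in `positions_a` that have at least one position
#' in `positions_b` within `threshold_um`, e.g. protein clusters against
#' antibody-tagged nucleosome marks on the same DNA. For `b` positions laid
#' down uniformly at linear density rho, the expected fraction is
#' `1 - exp(-2 * rho * threshold)`.
#'
#' @param positions_a,positions_b Positions along the DNA, um (`a`
#'   non-empty).
#' @param threshold_um Colocalization distance, um. Default 0.2 um,
#'   approximately the diffraction limit.
#' @return A list with `fraction`, `n_a`, `n_colocalized`.
#' @examples
#' colocalization_fraction(c(1, 5, 9), c(1.05, 4, 12), 0.2)
#' @export
colocalization_fraction <- function(positions_a, positions_b,
                                    threshold_um = 0.2) {
  check_number(threshold_um, "threshold_um", lower = 1e-300)
  if (!length(positions_a)) abort("`positions_a` must be non-empty")
  hit <- if (length(positions_b)) {
    map_dbl(positions_a, function(a) min(abs(a - positions_b))) <=
      threshold_um
  } else {
    rep(FALSE, length(positions_a))
  }
  list(fraction = mean(hit), n_a = length(positions_a),
       n_colocalized = sum(hit))
}
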
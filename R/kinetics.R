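#' Fit a first-order exponential to an assembly trace
#'
#' Nonlinear least squares of
#' `value = baseline + amplitude * (1 - exp(-k * (t - dead_time)))` to a
#' bulk kinetic trace (Levenberg-Marquardt). Initialization: baseline from
#' the earliest values, amplitude from the rise, and `k0 = 1/t_half` from
#' the trace's half-rise time; `k` is bounded to `[0, 10 / t_max]`.
#' Plate-reader mixing imposes a dead time before the first measurement;
#' `dead_time` (s) shifts the time origin accordingly (default 0; 15-20 s
#' is typical for manual mixing).
#'
#' A constant trace has no identifiable amplitude; it is returned as
#' `k = 0` with `flagged = TRUE` rather than an error.
#'
#' @param trace A tibble/data.frame with columns `time_s` and `value`
#'   (>= 5 finite points).
#' @param dead_time Dead time subtracted from `time_s`, s.
#' @return An object of class `first_order_fit` with `k_per_s`,
#'   `amplitude`, `baseline`, `rmse`, `flagged`, and the data with fitted
#'   values. [tidy()] and [glance()] methods are provided.
#' @examples
#' tr <- simulate_fret_trace(0.005, 1, 0.2, seq(0, 1000, 10))
#' fit_first_order(tr)
#' @export
fit_first_order <- function(trace, dead_time = 0) {
  check_number(dead_time, "dead_time", lower = 0)
  t <- trace$time_s - dead_time
  y <- trace$value
  keep <- is.finite(t) & is.finite(y) & t >= 0
  t <- t[keep]
  y <- y[keep]
  if (length(t) < 5) abort("need at least 5 finite points (after dead time)")
  rng <- diff(range(y))
  if (rng <= max(1e-12, 1e-9 * max(abs(y), 1))) {
    warn("constant trace: k = 0, amplitude unidentifiable")
    return(new_first_order_fit(0, 0, mean(y), y, rep(mean(y), length(y)),
                               t, flagged = TRUE))
  }
  base0 <- min(y)
  amp0 <- max(y) - base0
  half <- base0 + amp0 / 2
  i_half <- which(y >= half)[1]
  t_half <- if (!is.na(i_half) && t[i_half] > 0) t[i_half] else max(t) / 4
  k0 <- min(1 / t_half, 10 / max(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + amplitude * (1 - exp(-k * t)),
      start = list(baseline = base0, amplitude = amp0, k = k0),
      lower = c(baseline = -Inf, amplitude = 0, k = 0),
      upper = c(baseline = Inf, amplitude = Inf, k = 10 / max(t)),
      control = nls.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf(
        "exponential fit failed to converge (start: baseline=%.3g, amplitude=%.3g, k=%.3g): %s",
        base0, amp0, k0, conditionMessage(e)))
    })
  cf <- coef(fit)
  new_first_order_fit(unname(cf["k"]), unname(cf["amplitude"]),
                      unname(cf["baseline"]), y, predict(fit), t,
                      flagged = FALSE)
}

new_first_order_fit <- function(k, amplitude, baseline, y, fitted, t,
                                flagged) {
  structure(
    list(k_per_s = k, amplitude = amplitude, baseline = baseline,
         rmse = sqrt(mean((y - fitted)^2)), flagged = flagged,
         data = tibble(time_s = t, value = y, fitted = fitted)),
    class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf(
    "<first_order_fit> k = %.4g /s, amplitude = %.4g, baseline = %.4g, rmse = %.3g%s\n",
    x$k_per_s, x$amplitude, x$baseline, x$rmse,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Fit a Hill-form competition-binding curve
#'
#' Nonlinear least squares of `fraction_bound = 1 / (1 + (c/ic50)^hill)`
#' to a competition curve. With `normalize = TRUE` (default) the data are
#' first divided by the zero-competitor value so the fit operates on
#' fraction bound relative to the uncompeted plateau. If the curve never
#' crosses 0.5 the fit is still returned, with a wide-confidence warning.
#'
#' @param curve A tibble/data.frame with columns `concentration` and
#'   `fraction_bound` (>= 5 concentrations).
#' @param normalize Divide by the zero-competitor value first?
#' @return An object of class `competition_fit` with `ic50`, `hill`,
#'   `rmse`, and the data with fitted values. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' cc <- simulate_competition_curve(10, 2, c(0, 1, 3, 10, 30, 100))
#' fit_competition(cc)
#' @export
fit_competition <- function(curve, normalize = TRUE) {
  conc <- curve$concentration
  f <- curve$fraction_bound
  keep <- is.finite(conc) & is.finite(f) & conc >= 0
  conc <- conc[keep]
  f <- f[keep]
  if (length(conc) < 5) abort("need at least 5 concentrations")
  if (normalize) {
    ref <- if (any(conc == 0)) mean(f[conc == 0]) else max(f)
    if (ref <= 0) abort("cannot normalize: zero-competitor value <= 0")
    f <- f / ref
  }
  if (diff(range(f)) <= max(1e-12, 1e-9 * max(abs(f)))) {
    abort("no competition signal: fraction bound is constant, IC50/Hill unidentifiable")
  }
  if (all(f > 0.5)) {
    warn(paste0("curve never crosses 0.5: IC50 is extrapolated and its ",
                "confidence interval is wide"))
  }
  pos <- conc > 0
  ic50_0 <- {
    below <- which(f < 0.5 & pos)
    if (length(below)) {
      i <- below[1]
      j <- tail(which(f >= 0.5 & conc < conc[i]), 1)
      if (length(j)) sqrt(conc[i] * max(conc[j], min(conc[pos]))) else conc[i]
    } else {
      max(conc)
    }
  }
  df <- tibble(conc = conc[pos], f = f[pos])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ 1 / (1 + (conc / ic50)^hill),
      data = df,
      start = list(ic50 = ic50_0, hill = 1),
      lower = c(ic50 = 1e-12, hill = 1e-6),
      control = nls.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("competition fit failed to converge (start ic50=%.3g): %s",
                    ic50_0, conditionMessage(e)))
    })
  cf <- coef(fit)
  fitted_all <- 1 / (1 + (conc / cf["ic50"])^cf["hill"])
  structure(
    list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
         rmse = sqrt(mean((f - fitted_all)^2)),
         data = tibble(concentration = conc, fraction_bound = f,
                       fitted = fitted_all)),
    class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("<competition_fit> IC50 = %.4g, Hill = %.3g, rmse = %.3g\n",
              x$ic50, x$hill, x$rmse))
  invisible(x)
}

#' Protomer capacity of a DNA fragment
#'
#' How many protein copies fit on a fragment given the per-copy binding
#' footprint: `floor(length_bp / footprint_bp)`. With the ~15-bp footprint,
#' a 60-bp fragment holds the ~4 copies needed to initiate assembly and a
#' 150-bp fragment the ~10 copies of an optimal oligomer; fragments shorter
#' than one footprint hold none.
#'
#' @param length_bp Fragment length, bp (> 0).
#' @param footprint_bp Binding footprint per protomer, bp (default 15).
#' @return Integer number of protomers.
#' @examples
#' protomer_capacity(c(60, 150, 14))
#' @export
protomer_capacity <- function(length_bp, footprint_bp = 15) {
  if (any(length_bp <= 0) || any(footprint_bp <= 0)) {
    abort("lengths and footprint must be positive")
  }
  as.integer(floor(length_bp / footprint_bp))
}

#' Assembly rate versus DNA length
#'
#' Summarizes fitted assembly rates across DNA lengths: protomer capacity,
#' fold change relative to the shortest fragment and to the previous
#' length, and a saturation flag set where successive rates differ by less
#' than 10% (the antenna regime has ended and the optimal oligomer forms
#' regardless of extra length).
#'
#' @param fits A tibble/data.frame with columns `length_bp` and `k_per_s`
#'   (one fitted rate per length; >= 2 lengths).
#' @param footprint_bp Passed to [protomer_capacity()].
#' @return A tibble sorted by length with `length_bp`, `k_per_s`,
#'   `protomers`, `fold_vs_first`, `fold_vs_prev`, `saturated`.
#' @examples
#' rate_vs_length_summary(
#'   tibble::tibble(length_bp = c(60, 200, 600),
#'                  k_per_s = c(1e-4, 5e-3, 5.1e-3)))
#' @export
rate_vs_length_summary <- function(fits, footprint_bp = 15) {
  if (!all(c("length_bp", "k_per_s") %in% names(fits))) {
    abort("`fits` must have columns length_bp and k_per_s")
  }
  if (nrow(fits) < 2) abort("need rates for at least 2 lengths")
  fits %>%
    arrange(.data$length_bp) %>%
    mutate(protomers = protomer_capacity(.data$length_bp, footprint_bp),
           fold_vs_first = .data$k_per_s / dplyr::first(.data$k_per_s),
           fold_vs_prev = .data$k_per_s / lag(.data$k_per_s),
           saturated = !is.na(.data$fold_vs_prev) &
             abs(.data$fold_vs_prev - 1) < 0.1) %>%
    as_tibble()
}
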
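# broom-style tidiers for fitted objects.

#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("D_um2_per_s", "offset_um2"),
         estimate = c(x$D_um2_per_s, x$offset_um2),
         std.error = c(unname(sm[2, 2]) / 2, unname(sm[1, 2])))
}

#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble(D_um2_per_s = x$D_um2_per_s, offset_um2 = x$offset_um2,
         r_squared = x$r_squared, lag_min = x$fit_window[1],
         lag_max = x$fit_window[2], flagged = x$flagged)
}

#' @exportS3Method generics::tidy
tidy.drift_estimate <- function(x, ...) {
  tibble(term = "v_um_per_s", estimate = x$v_um_per_s)
}

#' @exportS3Method generics::glance
glance.drift_estimate <- function(x, ...) {
  tibble(v_um_per_s = x$v_um_per_s, n_trajectories = x$n_trajectories,
         total_time_s = x$total_time_s)
}

#' @exportS3Method generics::tidy
tidy.mc_search_result <- function(x, ...) x$times

#' @exportS3Method generics::glance
glance.mc_search_result <- function(x, ...) {
  tibble(median_s = x$median_s,
         mean_s = mean(x$times$time_s),
         n_reps = nrow(x$times),
         frac_censored = mean(x$times$censored),
         median_flagged = x$median_flagged,
         segment_um = x$config$segment_um)
}

#' @exportS3Method generics::tidy
tidy.first_order_fit <- function(x, ...) {
  tibble(term = c("k_per_s", "amplitude", "baseline"),
         estimate = c(x$k_per_s, x$amplitude, x$baseline))
}

#' @exportS3Method generics::glance
glance.first_order_fit <- function(x, ...) {
  tibble(k_per_s = x$k_per_s, amplitude = x$amplitude,
         baseline = x$baseline, rmse = x$rmse, flagged = x$flagged,
         n = nrow(x$data))
}

#' @exportS3Method generics::tidy
tidy.competition_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill"), estimate = c(x$ic50, x$hill))
}

#' @exportS3Method generics::glance
glance.competition_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, rmse = x$rmse, n = nrow(x$data))
}
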
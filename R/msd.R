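#' Time-averaged mean-square displacement of a trajectory
#'
#' For a single uniformly sampled track, computes the time-averaged MSD
#' `msd(k*dt) = mean((x[i+k] - x[i])^2)` over all ordered pairs at each lag
#' (overlapping pairs by default; `method = "nonoverlapping"` uses disjoint
#' pairs), up to `max_lag_fraction` of the track length. For 1D Brownian
#' motion with localization noise sigma the expectation is
#' `2*D*tau + 2*sigma^2`, which is what [fit_diffusion()] fits.
#'
#' @param traj A tibble with `time_s` and `position_um` for one particle
#'   (at least 4 points, uniformly sampled within 1% tolerance).
#' @param max_lag_fraction Largest lag as a fraction of track length.
#' @param max_lags Absolute cap on the number of lags (keeps long tracks
#'   cheap; only small lags are used for fitting anyway).
#' @param method `"overlapping"` (time-averaged, default) or
#'   `"nonoverlapping"`.
#'
#' @return A tibble of class `msd_curve` with `lag_s`, `msd_um2`, `n_pairs`.
#' @examples
#' cfg <- sim_config(D = 0.1, n_particles = 1, max_time_s = 10,
#'                   localization_sigma_um = 0, step_rule = "ignore", seed = 1)
#' tr <- simulate_trajectories(cfg, dna_substrate())
#' compute_msd(tr)
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25, max_lags = 100,
                        method = c("overlapping", "nonoverlapping")) {
  method <- match.arg(method)
  if ("particle_id" %in% names(traj) &&
      length(unique(traj$particle_id)) > 1) {
    abort("compute_msd() takes one trajectory; see estimate_diffusion()")
  }
  t <- traj$time_s
  x <- traj$position_um
  n <- length(x)
  if (n < 4) abort("need at least 4 time points")
  dts <- diff(t)
  dt0 <- median(dts)
  if (dt0 <= 0 || max(abs(dts - dt0)) > 0.01 * dt0) {
    abort(paste0("non-uniform sampling beyond 1% tolerance; ",
                 "resample the trajectory to a fixed frame interval first"))
  }
  K <- min(max(1L, floor(max_lag_fraction * (n - 1))), max_lags, n - 1L)
  lags <- seq_len(K)
  if (method == "overlapping") {
    msd <- map_dbl(lags, function(k) mean(diff(x, lag = k)^2))
    n_pairs <- n - lags
  } else {
    msd <- map_dbl(lags, function(k) {
      xs <- x[seq(1, n, by = k)]
      mean(diff(xs)^2)
    })
    n_pairs <- map_dbl(lags, function(k) length(seq(1, n, by = k)) - 1)
  }
  res <- tibble(lag_s = lags * dt0, msd_um2 = msd,
                n_pairs = as.integer(n_pairs))
  class(res) <- c("msd_curve", class(res))
  res
}

#' Ensemble mean-square displacement across a trajectory set
#'
#' MSD at each lag computed across particles from each track's first point,
#' `mean over particles of (x(t0 + tau) - x(t0))^2`. Exposed as the
#' ensemble-averaged alternative to the per-molecule time average of
#' [compute_msd()].
#'
#' @param trajs A `trajectory_set` tibble.
#' @param max_lags Number of lags to evaluate.
#' @return A tibble of class `msd_curve` (`n_pairs` = particles per lag).
#' @export
compute_msd_ensemble <- function(trajs, max_lags = 20) {
  by_p <- trajs %>%
    group_by(.data$particle_id) %>%
    mutate(disp2 = (.data$position_um - dplyr::first(.data$position_um))^2,
           lag_idx = .data$frame - dplyr::first(.data$frame)) %>%
    ungroup() %>%
    filter(.data$lag_idx >= 1, .data$lag_idx <= max_lags)
  if (!nrow(by_p)) abort("tracks too short for ensemble MSD")
  dt0 <- median(diff(sort(unique(trajs$time_s))))
  res <- by_p %>%
    group_by(.data$lag_idx) %>%
    summarise(msd_um2 = mean(.data$disp2), n_pairs = dplyr::n(),
              .groups = "drop") %>%
    mutate(lag_s = .data$lag_idx * dt0) %>%
    select("lag_s", "msd_um2", "n_pairs")
  class(res) <- c("msd_curve", class(res))
  res
}

#' Fit a diffusion coefficient to the linear regime of an MSD curve
#'
#' Weighted least-squares line `msd = 2*D*tau + b` over a lag window, with
#' weights equal to the number of displacement pairs per lag. The intercept
#' `b` absorbs the static localization-noise offset `2*sigma^2`. With
#' `window = "auto"` the fit starts from lags 2-10 and shrinks the upper
#' end until the weighted R-squared reaches 0.9 or three points remain, a
#' practical rule for staying inside the linear (unconfined) regime. A
#' negative fitted slope (noise-dominated track) is clipped to `D = 0` and
#' flagged rather than discarded.
#'
#' @param curve An [compute_msd()] result.
#' @param window `"auto"` or an integer vector of lag indices into `curve`.
#' @return An object of class `diffusion_fit` with elements
#'   `D_um2_per_s`, `offset_um2`, `fit_window`, `r_squared`, `flagged`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
fit_diffusion <- function(curve, window = "auto") {
  K <- nrow(curve)
  if (K < 3) abort("MSD curve too short to fit (need >= 3 lags)")
  if (length(stats::na.omit(unique(curve$lag_s))) < 2 ||
      var(curve$lag_s) == 0) {
    abort("singular fit: all lags equal")
  }
  if (identical(window, "auto")) {
    idx <- 2:min(10L, K)
    if (length(idx) < 3) idx <- seq_len(min(3L, K))
    repeat {
      fit <- lm(msd_um2 ~ lag_s, data = curve[idx, ], weights = n_pairs)
      r2 <- summary(fit)$r.squared
      if ((!is.na(r2) && r2 >= 0.9) || length(idx) <= 3) break
      idx <- idx[-length(idx)]
    }
  } else {
    idx <- as.integer(window)
    if (any(idx < 1 | idx > K)) abort("`window` outside the MSD curve")
    if (length(idx) < 3) abort("fit window needs >= 3 points")
    fit <- lm(msd_um2 ~ lag_s, data = curve[idx, ], weights = n_pairs)
    r2 <- summary(fit)$r.squared
  }
  slope <- unname(coef(fit)[2])
  flagged <- is.na(slope) || slope < 0
  D <- if (flagged) 0 else slope / 2
  structure(
    list(D_um2_per_s = D,
         offset_um2 = unname(coef(fit)[1]),
         fit_window = range(idx),
         r_squared = if (is.na(r2)) 0 else max(0, min(1, r2)),
         flagged = flagged,
         model = fit,
         curve = curve),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D = %.4g um^2/s, offset = %.4g um^2 (lags %d-%d, R2 = %.3f)%s\n",
    x$D_um2_per_s, x$offset_um2, x$fit_window[1], x$fit_window[2],
    x$r_squared, if (x$flagged) " [flagged: negative raw slope]" else ""))
  invisible(x)
}

#' Per-track diffusion estimates for a trajectory set
#'
#' Runs [compute_msd()] and [fit_diffusion()] on every particle and returns
#' one row per track. Tracks with fewer than 4 points are dropped with a
#' warning. The median of `D_um2_per_s` is the headline per-condition
#' diffusion coefficient.
#'
#' @param trajs A `trajectory_set` tibble.
#' @param max_lag_fraction,max_lags,method Passed to [compute_msd()].
#' @param window Passed to [fit_diffusion()].
#' @return A tibble with `particle_id`, `D_um2_per_s`, `offset_um2`,
#'   `r_squared`, `n_points`, `flagged`.
#' @examples
#' cfg <- sim_config(D = 0.026, n_particles = 20, max_time_s = 5,
#'                   mean_dwell_s = Inf, step_rule = "ignore", seed = 5)
#' ests <- estimate_diffusion(simulate_trajectories(cfg, dna_substrate()))
#' median(ests$D_um2_per_s)
#' @export
estimate_diffusion <- function(trajs, max_lag_fraction = 0.25,
                               max_lags = 20, method = "overlapping",
                               window = "auto") {
  ids <- unique(trajs$particle_id)
  rows <- map(ids, function(id) {
    tr <- trajs[trajs$particle_id == id, ]
    if (nrow(tr) < 4) return(NULL)
    curve <- compute_msd(tr, max_lag_fraction = max_lag_fraction,
                         max_lags = max_lags, method = method)
    if (nrow(curve) < 3) return(NULL)
    fit <- fit_diffusion(curve, window = window)
    tibble(particle_id = id, D_um2_per_s = fit$D_um2_per_s,
           offset_um2 = fit$offset_um2, r_squared = fit$r_squared,
           n_points = nrow(tr), flagged = fit$flagged)
  })
  dropped <- sum(map_dbl(rows, is.null))
  if (dropped > 0) {
    warn(sprintf("%d track(s) too short for MSD fitting were dropped",
                 dropped))
  }
  bind_rows(rows)
}
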
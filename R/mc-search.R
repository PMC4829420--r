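#' Configuration for the pairwise search-time Monte Carlo
#'
#' Two molecules diffuse on a DNA molecule carrying `N_occupancy` bound
#' molecules in total. Since all particles are equivalent, the DNA is
#' segmented into `N_occupancy` stretches of length `L_um / N_occupancy`
#' and the pair is simulated on one segment with periodic boundaries: the
#' effective separation is the absolute distance modulo the segment length,
#' folded to the shorter arc. A replicate ends when the separation falls
#' below the capture radius (10 nm by default, the distance at which two
#' molecules are considered met and dimerized).
#'
#' The time step must satisfy the step-resolution rule
#' `sqrt(2*D*dt) + drift_v*dt < capture_radius_um`; otherwise a single step
#' could jump across the capture zone and first passages would be missed.
#' This is enforced as an error. The default `dt = 0.001` s is the largest
#' round value obeying the rule at the default D and capture radius.
#'
#' @param L_um Total DNA length, um. Default is the lambda genome
#'   (48502 bp) at the stretched conversion of [dna_substrate()].
#' @param N_occupancy Total number of bound molecules (>= 2).
#' @param D Diffusion coefficient of each molecule, um^2/s.
#' @param drift_v Flow drift speed, um/s.
#' @param advection `"common"` (default): drift advects both walkers, the
#'   literal reading of adding `v*dt` to each random step, which leaves the
#'   pair separation unaffected; `"single"`: drift advects one walker only,
#'   a sensitivity-analysis variant in which drift does change the search.
#' @param dt Time step, s.
#' @param capture_radius_um Capture (encounter) distance, um.
#' @param n_reps Number of replicates.
#' @param max_time_s Censoring horizon, s.
#' @param seed Integer seed (mandatory).
#'
#' @return An object of class `mc_search_config`.
#' @examples
#' cfg <- mc_search_config(N_occupancy = 50, n_reps = 100, seed = 1)
#' @export
mc_search_config <- function(L_um = 48502 * 0.34 * 0.8 / 1000,
                             N_occupancy = 2,
                             D = 0.026,
                             drift_v = 0,
                             advection = c("common", "single"),
                             dt = 0.001,
                             capture_radius_um = 0.01,
                             n_reps = 2000,
                             max_time_s = 1e4,
                             seed) {
  if (missing(seed)) abort("`seed` is mandatory in mc_search_config()")
  advection <- match.arg(advection)
  check_number(L_um, "L_um", lower = 1e-12)
  check_number(N_occupancy, "N_occupancy", lower = 2)
  check_number(D, "D", lower = 0)
  check_number(drift_v, "drift_v", lower = 0)
  check_number(dt, "dt", lower = 1e-12)
  check_number(capture_radius_um, "capture_radius_um", lower = 1e-12)
  check_number(n_reps, "n_reps", lower = 1)
  check_number(max_time_s, "max_time_s", lower = dt)
  check_number(seed, "seed", lower = 0, upper = .Machine$integer.max)
  segment <- L_um / N_occupancy
  if (capture_radius_um >= segment) {
    abort("capture radius must be smaller than the segment length L/N")
  }
  step <- sqrt(2 * D * dt) + drift_v * dt
  if (step >= capture_radius_um) {
    abort(sprintf(
      paste0("step-resolution rule violated: sqrt(2*D*dt) + drift_v*dt = ",
             "%.4g um >= capture_radius_um = %.4g um; reduce dt"),
      step, capture_radius_um), class = "scanseek_step_rule")
  }
  structure(
    list(L_um = L_um, N_occupancy = as.integer(N_occupancy), D = D,
         drift_v = drift_v, advection = advection, dt = dt,
         capture_radius_um = capture_radius_um, n_reps = as.integer(n_reps),
         max_time_s = max_time_s, seed = as.integer(seed),
         segment_um = segment),
    class = "mc_search_config")
}

#' @export
print.mc_search_config <- function(x, ...) {
  cat(sprintf(
    "<mc_search_config> L=%.3g um, N=%d (segment %.3g um), D=%g um^2/s\n",
    x$L_um, x$N_occupancy, x$segment_um, x$D))
  cat(sprintf("  drift=%g um/s (%s), dt=%g s, capture=%g um, %d reps\n",
              x$drift_v, x$advection, x$dt, x$capture_radius_um, x$n_reps))
  invisible(x)
}

#' Simulate pairwise search times on occupied DNA
#'
#' Runs the Monte-Carlo pair search defined by [mc_search_config()]. Both
#' walkers start uniformly at random on the segment; each step adds
#' `drift_v*dt` (to both walkers for common advection, to one for the
#' single-walker variant) plus independent Gaussian increments
#' `sqrt(2*D*dt) * xi`. Positions wrap on the segment and the separation is
#' evaluated as the shorter arc `min(d, segment - d)` of
#' `d = |x1 - x2| mod segment`. A replicate ends when the separation drops
#' to the capture radius; replicates still searching at `max_time_s` are
#' censored. More than 90% censoring is an error (increase `max_time_s`);
#' with more than 50% censoring the median is flagged unreliable.
#'
#' @param config An [mc_search_config()].
#' @return An object of class `mc_search_result`: a list with `times` (a
#'   tibble `rep`, `time_s`, `censored`), `median_s` (computed on
#'   uncensored replicates), `median_flagged`, and the config. [tidy()]
#'   and [glance()] methods are provided.
#' @examples
#' cfg <- mc_search_config(L_um = 10, N_occupancy = 20, n_reps = 200,
#'                         max_time_s = 100, seed = 42)
#' res <- simulate_search_time(cfg)
#' glance(res)
#' @export
simulate_search_time <- function(config) {
  stopifnot(inherits(config, "mc_search_config"))
  seg <- config$segment_um
  a <- config$capture_radius_um
  dt <- config$dt
  sd_step <- sqrt(2 * config$D * dt)
  vdt <- config$drift_v * dt
  n <- config$n_reps
  max_steps <- ceiling(config$max_time_s / dt)

  seed_rng(config$seed)
  x1 <- runif(n, 0, seg)
  x2 <- runif(n, 0, seg)
  times <- rep(NA_real_, n)
  sep <- pmin(abs(x1 - x2) %% seg, seg - abs(x1 - x2) %% seg)
  done <- sep <= a
  times[done] <- 0
  active <- which(!done)
  step <- 0L
  while (length(active) && step < max_steps) {
    step <- step + 1L
    m <- length(active)
    x1[active] <- (x1[active] + vdt + rnorm(m, 0, sd_step)) %% seg
    if (config$advection == "common") {
      x2[active] <- (x2[active] + vdt + rnorm(m, 0, sd_step)) %% seg
    } else {
      x2[active] <- (x2[active] + rnorm(m, 0, sd_step)) %% seg
    }
    d <- abs(x1[active] - x2[active]) %% seg
    sep_a <- pmin(d, seg - d)
    captured <- sep_a <= a
    if (any(captured)) {
      times[active[captured]] <- step * dt
      active <- active[!captured]
    }
  }
  censored <- is.na(times)
  times[censored] <- config$max_time_s
  frac_cens <- mean(censored)
  if (frac_cens > 0.9) {
    abort(sprintf(
      "%.0f%% of replicates censored at max_time_s = %g s; increase max_time_s",
      100 * frac_cens, config$max_time_s))
  }
  med <- median(times[!censored])
  structure(
    list(times = tibble(rep = seq_len(n), time_s = times,
                        censored = censored),
         median_s = med,
         median_flagged = frac_cens > 0.5,
         config = config),
    class = "mc_search_result")
}

#' @export
print.mc_search_result <- function(x, ...) {
  cat(sprintf(
    "<mc_search_result> %d reps, median search time %.4g s (%.1f%% censored)%s\n",
    nrow(x$times), x$median_s, 100 * mean(x$times$censored),
    if (x$median_flagged) " [flagged: >50% censored]" else ""))
  invisible(x)
}

#' Analytic mean first-passage time for a diffusing pair on a ring
#'
#' Independent closed-form oracle for [simulate_search_time()]. For two
#' walkers on a ring of circumference `l`, the relative coordinate diffuses
#' with coefficient 2D; the mean first-passage time to contact from a
#' uniformly random start is `l^2 / (24 * D)`. A finite capture radius `a`
#' is handled as an effective circumference `l - 2a` (accurate to O(a/l);
#' the exact uniform-start mean including instant captures is
#' `(l - 2a)^3 / (24 * D * l)`).
#'
#' @param segment_um Ring circumference (= DNA segment length), um.
#' @param D Per-walker diffusion coefficient, um^2/s.
#' @param capture_radius_um Capture radius, um (default 0).
#' @return Expected search time, s.
#' @examples
#' analytic_pair_mfpt(1, 0.026)   # ~1.60 s
#' @export
analytic_pair_mfpt <- function(segment_um, D, capture_radius_um = 0) {
  check_number(segment_um, "segment_um", lower = 1e-12)
  check_number(D, "D", lower = 1e-300)
  check_number(capture_radius_um, "capture_radius_um", lower = 0)
  l_eff <- segment_um - 2 * capture_radius_um
  if (l_eff <= 0) return(0)
  l_eff^2 / (24 * D)
}

#' Effect of flow drift on the pair search time
#'
#' Re-runs [simulate_search_time()] at each drift value with matched seeds
#' (the same random increments) and reports median search times and their
#' ratios to the zero-drift reference, with bootstrap confidence intervals.
#' With common advection the pair separation is independent of drift, so
#' the matched-seed ratio is exactly 1; the single-walker variant breaks
#' this invariance.
#'
#' @param config An [mc_search_config()]; its `drift_v` is overridden.
#' @param drift_values Numeric drift speeds, um/s; must include 0.
#' @param n_boot Bootstrap resamples for the ratio CI.
#' @return A tibble with `drift_v`, `median_s`, `ratio_vs_zero`,
#'   `ratio_lo`, `ratio_hi`, `frac_censored`.
#' @export
flow_effect <- function(config, drift_values, n_boot = 1000) {
  stopifnot(inherits(config, "mc_search_config"))
  if (length(drift_values) < 2 || !any(drift_values == 0)) {
    abort("`drift_values` needs >= 2 values, one of them 0")
  }
  runs <- map(drift_values, function(v) {
    cfg <- config
    cfg$drift_v <- v
    # re-validate the step rule at this drift
    cfg <- mc_search_config(L_um = cfg$L_um, N_occupancy = cfg$N_occupancy,
                            D = cfg$D, drift_v = v, advection = cfg$advection,
                            dt = cfg$dt,
                            capture_radius_um = cfg$capture_radius_um,
                            n_reps = cfg$n_reps, max_time_s = cfg$max_time_s,
                            seed = cfg$seed)
    simulate_search_time(cfg)
  })
  ref <- runs[[which(drift_values == 0)[1]]]$times$time_s
  seed_rng(config$seed + 1L)
  rows <- map2(drift_values, runs, function(v, r) {
    tt <- r$times$time_s
    ratio <- median(tt) / median(ref)
    boots <- map_dbl(seq_len(n_boot), function(b) {
      idx <- sample.int(length(tt), replace = TRUE)
      median(tt[idx]) / median(ref[idx])
    })
    tibble(drift_v = v, median_s = median(tt), ratio_vs_zero = ratio,
           ratio_lo = unname(quantile(boots, 0.025)),
           ratio_hi = unname(quantile(boots, 0.975)),
           frac_censored = mean(r$times$censored))
  })
  bind_rows(rows)
}

#' Median search time as a function of DNA occupancy
#'
#' Runs the pair search at each total occupancy N. The segment length is
#' L/N, and since the diffusive search time scales with the square of the
#' distance to cover, medians fall roughly fourfold when N doubles.
#'
#' @param config An [mc_search_config()]; its `N_occupancy` is overridden.
#' @param N_values Integer occupancies (all >= 2).
#' @return A tibble with `N`, `segment_um`, `median_s`, `mean_s`,
#'   `frac_censored`, `analytic_mfpt_s` (the [analytic_pair_mfpt()] oracle
#'   at the same segment and capture radius).
#' @examples
#' cfg <- mc_search_config(n_reps = 200, max_time_s = 200, seed = 3)
#' occupancy_sweep(cfg, c(10, 50, 100))
#' @export
occupancy_sweep <- function(config, N_values) {
  stopifnot(inherits(config, "mc_search_config"))
  if (any(N_values < 2)) abort("all N values must be >= 2")
  rows <- map(N_values, function(N) {
    cfg <- mc_search_config(L_um = config$L_um, N_occupancy = N,
                            D = config$D, drift_v = config$drift_v,
                            advection = config$advection, dt = config$dt,
                            capture_radius_um = config$capture_radius_um,
                            n_reps = config$n_reps,
                            max_time_s = config$max_time_s,
                            seed = config$seed + N)
    r <- simulate_search_time(cfg)
    tibble(N = as.integer(N), segment_um = cfg$segment_um,
           median_s = r$median_s, mean_s = mean(r$times$time_s),
           frac_censored = mean(r$times$censored),
           analytic_mfpt_s = analytic_pair_mfpt(cfg$segment_um, cfg$D,
                                                cfg$capture_radius_um))
  })
  bind_rows(rows)
}

#' Time-step convergence diagnostic for the pair search
#'
#' Checks that the Monte-Carlo search time is converged in `dt` by a
#' matched-path Richardson comparison. The walk is simulated at `dt/2`;
#' because Gaussian increments compose exactly, the same paths observed
#' only at every other step are a faithful `dt`-step simulation, so
#' checking capture at every step versus every other step isolates the
#' pure discretization effect of halving `dt`, with the path randomness
#' cancelled. The reported ratio of medians should be close to 1 when
#' `dt` resolves the capture radius.
#'
#' @param config An [mc_search_config()]; the comparison is between
#'   `config$dt` (coarse) and `config$dt / 2` (fine).
#' @return A one-row tibble with `median_fine_s`, `median_coarse_s`,
#'   `median_ratio` (coarse/fine), `mean_ratio`, `n_reps`.
#' @examples
#' cfg <- mc_search_config(L_um = 2, n_reps = 500, seed = 9)
#' dt_convergence_check(cfg)
#' @export
dt_convergence_check <- function(config) {
  stopifnot(inherits(config, "mc_search_config"))
  seg <- config$segment_um
  a <- config$capture_radius_um
  dtf <- config$dt / 2
  sd_step <- sqrt(2 * config$D * dtf)
  vdt <- config$drift_v * dtf
  n <- config$n_reps
  max_steps <- 2L * ceiling(config$max_time_s / config$dt)
  seed_rng(config$seed)
  x1 <- runif(n, 0, seg)
  x2 <- runif(n, 0, seg)
  t_fine <- rep(NA_real_, n)
  t_coarse <- rep(NA_real_, n)
  sep0 <- pmin(abs(x1 - x2) %% seg, seg - abs(x1 - x2) %% seg)
  t_fine[sep0 <= a] <- 0
  t_coarse[sep0 <= a] <- 0
  active <- which(is.na(t_coarse))
  step <- 0L
  while (length(active) && step < max_steps) {
    step <- step + 1L
    m <- length(active)
    x1[active] <- (x1[active] + vdt + rnorm(m, 0, sd_step)) %% seg
    if (config$advection == "common") {
      x2[active] <- (x2[active] + vdt + rnorm(m, 0, sd_step)) %% seg
    } else {
      x2[active] <- (x2[active] + rnorm(m, 0, sd_step)) %% seg
    }
    d <- abs(x1[active] - x2[active]) %% seg
    cap <- pmin(d, seg - d) <= a
    if (any(cap)) {
      idx <- active[cap]
      newf <- idx[is.na(t_fine[idx])]
      t_fine[newf] <- step * dtf
      if (step %% 2L == 0L) {
        t_coarse[idx] <- step * dtf
        active <- setdiff(active, idx)
      }
    }
  }
  cens <- is.na(t_fine) | is.na(t_coarse)
  if (mean(cens) > 0.9) {
    abort("over 90% of replicates censored; increase max_time_s")
  }
  tf <- t_fine[!cens]
  tc <- t_coarse[!cens]
  tibble(median_fine_s = median(tf), median_coarse_s = median(tc),
         median_ratio = median(tc) / median(tf),
         mean_ratio = mean(tc) / mean(tf),
         n_reps = length(tf))
}
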
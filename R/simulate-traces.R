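#' Simulate a first-order FRET assembly trace
#'
#' Bulk oligomerization kinetics read out as a FRET acceptor/donor emission
#' ratio follow a single-exponential approach to plateau,
#' `value(t) = baseline + amplitude * (1 - exp(-k * t))`, on which Gaussian
#' plate-reader noise is superimposed.
#'
#' @param k Observed assembly rate constant, 1/s (>= 0).
#' @param amplitude Plateau rise above baseline (FRET-ratio units).
#' @param baseline Signal before assembly (FRET-ratio units).
#' @param times_s Non-negative, increasing measurement times, s.
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_s` and `value`.
#' @examples
#' tr <- simulate_fret_trace(0.01, 1, 0.2, seq(0, 600, 10), 0.02, seed = 1)
#' @export
simulate_fret_trace <- function(k, amplitude, baseline, times_s,
                                noise_sd = 0, seed = NULL) {
  check_number(k, "k", lower = 0)
  check_number(amplitude, "amplitude")
  check_number(baseline, "baseline")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(times_s) < 1 || any(times_s < 0) ||
      any(diff(times_s) <= 0)) {
    abort("`times_s` must be non-negative and strictly increasing")
  }
  seed_rng(seed)
  mu <- baseline + amplitude * (1 - exp(-k * times_s))
  tibble(time_s = times_s,
         value = mu + rnorm(length(times_s), 0, noise_sd))
}

#' Simulate a competition-binding curve
#'
#' Fraction of probe DNA remaining protein-bound as a function of competitor
#' concentration, following the Hill-form displacement curve
#' `1 / (1 + (c / ic50)^hill)`, plus Gaussian noise.
#'
#' @param ic50 Competitor concentration at half-maximal displacement
#'   (same units as `concentrations`, conventionally ug/ml of DNA).
#' @param hill Hill coefficient (> 0).
#' @param concentrations Non-negative competitor concentrations.
#' @param noise_sd Gaussian noise SD on the bound fraction (>= 0).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `concentration` and `fraction_bound`.
#' @examples
#' simulate_competition_curve(10, 2, c(0, 1, 10, 100))
#' @export
simulate_competition_curve <- function(ic50, hill, concentrations,
                                       noise_sd = 0, seed = NULL) {
  check_number(ic50, "ic50", lower = 1e-12)
  check_number(hill, "hill", lower = 1e-12)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (any(concentrations < 0)) abort("`concentrations` must be >= 0")
  seed_rng(seed)
  f <- 1 / (1 + (concentrations / ic50)^hill)
  tibble(concentration = concentrations,
         fraction_bound = f + rnorm(length(f), 0, noise_sd))
}

#' Simulate cluster fluorescence intensities
#'
#' The intensity of an n-molecule cluster is the sum of n independent
#' single-fluorophore intensities, each Gaussian with mean `unit_mean` and
#' coefficient of variation `unit_cv`, truncated at zero. This is the
#' statistical model behind converting measured cluster intensities back to
#' molecule counts with [cluster_sizes()].
#'
#' @param true_sizes Integer vector of true molecule counts (>= 1), one per
#'   cluster.
#' @param unit_mean Mean single-fluorophore intensity, a.u. (> 0).
#' @param unit_cv Coefficient of variation of the single-fluorophore
#'   intensity (>= 0).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `true_size` and `intensity_au`.
#' @examples
#' simulate_cluster_intensities(rep(8, 5), 100, 0.3, seed = 1)
#' @export
simulate_cluster_intensities <- function(true_sizes, unit_mean, unit_cv,
                                         seed = NULL) {
  if (any(true_sizes < 1) || any(true_sizes != round(true_sizes))) {
    abort("`true_sizes` must be integers >= 1")
  }
  check_number(unit_mean, "unit_mean", lower = 1e-12)
  check_number(unit_cv, "unit_cv", lower = 0)
  seed_rng(seed)
  intens <- map_dbl(true_sizes, function(n) {
    sum(pmax(rnorm(n, unit_mean, unit_cv * unit_mean), 0))
  })
  tibble(true_size = as.integer(true_sizes), intensity_au = intens)
}

#' Simulate growing clusters on DNA
#'
#' Emulates the time-resolved clustering seen at elevated protein
#' concentration: each cluster starts as a bound seed, gains molecules as a
#' Poisson process, and diffuses with a size-dependent coefficient
#' `D_mono * n^(-size_exponent)`, so growing clusters slow down and become
#' effectively immobile. By default the addition rate is independent of the
#' current cluster size (`rate_size_exponent = 0`), the mechanism consistent
#' with non-cooperative assembly; setting a positive exponent makes growth
#' size-promoted for sensitivity analyses.
#'
#' @param n_clusters Number of clusters to simulate.
#' @param t_max_s Duration, s.
#' @param dt Sampling interval, s.
#' @param addition_rate Baseline molecule-addition rate, 1/s.
#' @param D_mono Monomer diffusion coefficient, um^2/s.
#' @param size_exponent Exponent of the D ~ n^(-a) mobility decay
#'   (default 1, inverse proportionality).
#' @param rate_size_exponent Exponent b of the size dependence of the
#'   addition rate, rate ~ n^b (default 0: size-independent).
#' @param start_size Initial molecules per cluster; a scalar or one value
#'   per cluster.
#' @param L_um Length of DNA available, um.
#' @param unit_mean,unit_cv Single-fluorophore intensity model, as in
#'   [simulate_cluster_intensities()].
#' @param seed Integer seed (mandatory).
#'
#' @return A tibble of cluster records: `cluster_id`, `frame`, `time_s`,
#'   `position_um`, `n_molecules`, `intensity_au`.
#' @examples
#' recs <- simulate_cluster_growth(5, t_max_s = 30, seed = 2)
#' @export
simulate_cluster_growth <- function(n_clusters,
                                    t_max_s = 60,
                                    dt = 1,
                                    addition_rate = 0.1,
                                    D_mono = 0.026,
                                    size_exponent = 1,
                                    rate_size_exponent = 0,
                                    start_size = 1,
                                    L_um = 13.2,
                                    unit_mean = 1000,
                                    unit_cv = 0.3,
                                    seed) {
  if (missing(seed)) abort("`seed` is mandatory in simulate_cluster_growth()")
  check_number(n_clusters, "n_clusters", lower = 1)
  check_number(t_max_s, "t_max_s", lower = dt)
  check_number(dt, "dt", lower = 1e-12)
  check_number(addition_rate, "addition_rate", lower = 0)
  check_number(D_mono, "D_mono", lower = 0)
  if (any(start_size < 1)) abort("`start_size` must be >= 1")
  start_size <- rep_len(start_size, n_clusters)
  seed_rng(seed)
  n_frames <- floor(t_max_s / dt) + 1L
  out <- vector("list", n_clusters)
  for (i in seq_len(n_clusters)) {
    n <- numeric(n_frames)
    x <- numeric(n_frames)
    n[1] <- start_size[i]
    x[1] <- runif(1, 0, L_um)
    for (k in 2:n_frames) {
      n[k] <- n[k - 1] +
        rpois(1, addition_rate * n[k - 1]^rate_size_exponent * dt)
      Dk <- D_mono * n[k]^(-size_exponent)
      x[k] <- reflect_into(x[k - 1] + rnorm(1, 0, sqrt(2 * Dk * dt)), 0, L_um)
    }
    inten <- pmax(rnorm(n_frames, n * unit_mean,
                        sqrt(n) * unit_cv * unit_mean), 0)
    out[[i]] <- tibble(cluster_id = i, frame = seq_len(n_frames) - 1L,
                       time_s = (seq_len(n_frames) - 1L) * dt,
                       position_um = x, n_molecules = as.integer(n),
                       intensity_au = inten)
  }
  bind_rows(out)
}
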
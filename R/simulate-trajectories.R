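#' Simulate 1D trajectories of DNA-bound particles
#'
#' Generates Brownian trajectories of particles bound to a stretched DNA
#' molecule, the synthetic stand-in for single-molecule TIRF tracking data.
#' Each particle binds at a position drawn uniformly along the DNA, moves by
#' the Euler-Maruyama update `x <- x + drift_v*dt + sqrt(2*D*dt)*xi` with
#' standard-normal `xi`, is reflected at nucleosome barriers and at tethered
#' DNA ends, and unbinds after an exponentially distributed dwell time.
#' On single-tethered DNA the far end is a free tip: a particle reaching it
#' either sticks there until unbinding (default) or unbinds immediately,
#' per `config$tip_behavior`. Flow drift is applied only when `flow_on` and
#' the substrate is single-tethered (a doubly anchored molecule is imaged
#' without flow). Recorded positions are perturbed post hoc by i.i.d.
#' Gaussian localization noise of width `config$localization_sigma_um`.
#'
#' Reproducibility: one master RNG stream is seeded from `config$seed` and
#' per-particle sub-seeds are drawn from it, so identical configurations
#' reproduce identical trajectory sets bit for bit.
#'
#' @param config A [sim_config()].
#' @param substrate A [dna_substrate()].
#' @param flow_on Logical; whether buffer flow (and hence drift) is applied.
#'
#' @return A tibble of class `trajectory_set` with columns `particle_id`,
#'   `frame`, `time_s`, `position_um`, `intensity_au`, and the substrate
#'   stored in attribute `"substrate"`.
#' @examples
#' cfg <- sim_config(D = 0.026, n_particles = 5, max_time_s = 5, seed = 7)
#' trajs <- simulate_trajectories(cfg, dna_substrate())
#' dplyr::count(trajs, particle_id)
#' @export
simulate_trajectories <- function(config, substrate, flow_on = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(substrate, "dna_substrate"))
  check_flag(flow_on, "flow_on")
  L <- substrate$length_um
  drift <- if (flow_on && substrate$anchoring == "single_tethered") {
    config$drift_v
  } else {
    0
  }
  seed_rng(config$seed)
  subseeds <- derive_subseeds(config$n_particles)
  out <- vector("list", config$n_particles)
  for (i in seq_len(config$n_particles)) {
    set.seed(subseeds[i])
    out[[i]] <- simulate_one_track(i, config, substrate, drift)
  }
  res <- bind_rows(out)
  attr(res, "substrate") <- substrate
  class(res) <- c("trajectory_set", class(res))
  res
}

# One particle. Uses the exact folding identity (reflected path = triangular
# fold of the free path) when there is no drift, no tip absorption and no
# leaky barriers; otherwise steps through time explicitly.
simulate_one_track <- function(id, config, substrate, drift) {
  L <- substrate$length_um
  dt <- config$dt
  dwell <- if (is.finite(config$mean_dwell_s)) {
    rexp(1, rate = 1 / config$mean_dwell_s)
  } else {
    Inf
  }
  duration <- min(dwell, config$max_time_s)
  n_steps <- max(0L, floor(duration / dt))
  x0 <- runif(1, 0, L)
  free_tip <- substrate$anchoring == "single_tethered"
  edges <- segment_edges(substrate)
  leaky <- config$barrier_pass_prob > 0 && length(substrate$barriers_um) > 0
  if (leaky) {
    lo <- 0
    hi <- L
  } else {
    seg <- segment_of(x0, substrate)
    lo <- edges[seg]
    hi <- edges[seg + 1]
  }
  tip_in_segment <- free_tip && hi >= L
  if (n_steps == 0L) {
    x <- x0
  } else if (drift == 0 && !tip_in_segment && !leaky) {
    steps <- rnorm(n_steps, 0, sqrt(2 * config$D * dt))
    x <- c(x0, reflect_into(x0 + cumsum(steps), lo, hi))
  } else {
    x <- numeric(n_steps + 1L)
    x[1] <- x0
    sd_step <- sqrt(2 * config$D * dt)
    barriers <- substrate$barriers_um
    pos <- x0
    stuck <- FALSE
    k <- 2L
    while (k <= n_steps + 1L) {
      if (stuck) {
        x[k:(n_steps + 1L)] <- L
        k <- n_steps + 2L
        break
      }
      cand <- pos + drift * dt + rnorm(1, 0, sd_step)
      if (leaky) {
        # At most one barrier interaction per step (steps are small against
        # barrier spacing by the step-resolution rule).
        crossed <- barriers[barriers > min(pos, cand) &
                              barriers < max(pos, cand)]
        if (length(crossed) && runif(1) > config$barrier_pass_prob) {
          b <- if (cand > pos) min(crossed) else max(crossed)
          cand <- 2 * b - cand
        }
      }
      if (cand < lo) cand <- reflect_into(cand, lo, hi)
      if (cand >= hi) {
        if (tip_in_segment && cand >= L) {
          if (config$tip_behavior == "stick") {
            pos <- L
            x[k] <- L
            stuck <- TRUE
            k <- k + 1L
            next
          } else {  # unbind at the tip: truncate the track here
            x <- x[1:(k - 1L)]
            n_steps <- k - 2L
            break
          }
        }
        cand <- reflect_into(cand, lo, hi)
      }
      pos <- cand
      x[k] <- cand
      k <- k + 1L
    }
  }
  n <- length(x)
  times <- (seq_len(n) - 1L) * dt
  obs <- x + rnorm(n, 0, config$localization_sigma_um)
  inten <- rnorm(n, config$intensity_mean_au,
                 config$intensity_cv * config$intensity_mean_au)
  inten <- pmax(inten, 0)
  tibble(
    particle_id = id,
    frame = seq_len(n) - 1L,
    time_s = times,
    position_um = obs,
    intensity_au = inten
  )
}

#' Dwell-time summary of a trajectory set
#'
#' Observed bound durations per particle (time of the last recorded frame
#' minus the first), with the median across particles. Durations are capped
#' by the acquisition window, so for long-lived binders these are lower
#' bounds, as in the experiment.
#'
#' @param trajs A `trajectory_set` tibble.
#' @return A tibble with `particle_id` and `duration_s`; the median duration
#'   and number of tracks are stored in attributes `"median_s"` and `"n"`.
#' @export
dwell_summary <- function(trajs) {
  res <- trajs %>%
    group_by(.data$particle_id) %>%
    summarise(duration_s = max(.data$time_s) - min(.data$time_s),
              .groups = "drop")
  attr(res, "median_s") <- median(res$duration_s)
  attr(res, "n") <- nrow(res)
  res
}
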
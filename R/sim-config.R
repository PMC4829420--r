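#' Configuration for the Brownian trajectory generator
#'
#' Collects and validates the physical and imaging parameters for
#' [simulate_trajectories()]. The defaults reflect the single-molecule
#' conditions the analysis pipeline is built around: a slowly diffusing
#' DNA-bound sensor (D = 0.026 um^2/s), a weak flow-induced drift
#' (0.127 um/s when flow is on), dwell times of several seconds, and a
#' localization precision of 30 nm.
#'
#' The step-resolution rule
#' `sqrt(2 * D * dt) + drift_v * dt < capture_radius_um` guarantees that a
#' single step cannot silently jump across the encounter distance. It is
#' binding where encounters are actually resolved ([mc_search_config()]
#' enforces it as an error); here trajectories are recorded at the imaging
#' frame interval and no capture events are simulated, so by default a
#' violation only raises a warning. Set `step_rule = "error"` to make it a
#' configuration error, or `"ignore"` to silence it.
#'
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param drift_v Flow-induced drift speed along the DNA, um/s (>= 0).
#'   Applied only for single-tethered substrates with flow on.
#' @param dt Simulation time step, s.
#' @param n_particles Number of trajectories to generate.
#' @param mean_dwell_s Mean of the exponential bound-state dwell time, s.
#'   `Inf` disables unbinding so every track runs to `max_time_s`.
#' @param capture_radius_um Encounter distance for two particles to be
#'   considered met, um. Default 0.01 um (10 nm).
#' @param localization_sigma_um Gaussian localization noise added to the
#'   recorded positions, um.
#' @param max_time_s Hard cap on track duration, s.
#' @param intensity_mean_au,intensity_cv Per-frame single-fluorophore
#'   intensity mean (a.u.) and coefficient of variation.
#' @param tip_behavior What a particle does on reaching the free tip of a
#'   single-tethered molecule: `"stick"` (default; it stays at the tip until
#'   unbinding) or `"unbind"` (track ends there).
#' @param barrier_pass_prob Probability that a step crossing a nucleosome
#'   barrier is allowed through instead of reflected. Default 0 (perfectly
#'   reflecting barriers).
#' @param step_rule How to treat a violation of the step-resolution rule:
#'   `"warn"` (default), `"error"`, or `"ignore"`.
#' @param seed Integer seed; mandatory so that runs are reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(D = 0.026, n_particles = 10, seed = 1)
#' @export
sim_config <- function(D = 0.026,
                       drift_v = 0,
                       dt = 0.01,
                       n_particles = 1,
                       mean_dwell_s = 10,
                       capture_radius_um = 0.01,
                       localization_sigma_um = 0.03,
                       max_time_s = 60,
                       intensity_mean_au = 1000,
                       intensity_cv = 0.3,
                       tip_behavior = c("stick", "unbind"),
                       barrier_pass_prob = 0,
                       step_rule = c("warn", "error", "ignore"),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config()")
  tip_behavior <- match.arg(tip_behavior)
  step_rule <- match.arg(step_rule)
  check_number(D, "D", lower = 0)
  check_number(drift_v, "drift_v", lower = 0)
  check_number(dt, "dt", lower = 1e-12)
  check_number(n_particles, "n_particles", lower = 1)
  check_number(mean_dwell_s, "mean_dwell_s", lower = 1e-12, allow_inf = TRUE)
  check_number(capture_radius_um, "capture_radius_um", lower = 1e-12)
  check_number(localization_sigma_um, "localization_sigma_um", lower = 0)
  check_number(max_time_s, "max_time_s", lower = 1e-12)
  check_number(intensity_mean_au, "intensity_mean_au", lower = 0)
  check_number(intensity_cv, "intensity_cv", lower = 0)
  check_number(barrier_pass_prob, "barrier_pass_prob", lower = 0, upper = 1)
  check_number(seed, "seed", lower = 0, upper = .Machine$integer.max)
  step <- sqrt(2 * D * dt) + drift_v * dt
  if (step >= capture_radius_um && step_rule != "ignore") {
    msg <- sprintf(
      paste0("step-resolution rule violated: sqrt(2*D*dt) + drift_v*dt = ",
             "%.4g um >= capture_radius_um = %.4g um; reduce dt"),
      step, capture_radius_um)
    if (step_rule == "error") abort(msg, class = "scanseek_step_rule")
    warn(msg, class = "scanseek_step_rule")
  }
  structure(
    list(D = D, drift_v = drift_v, dt = dt, n_particles = n_particles,
         mean_dwell_s = mean_dwell_s, capture_radius_um = capture_radius_um,
         localization_sigma_um = localization_sigma_um,
         max_time_s = max_time_s, intensity_mean_au = intensity_mean_au,
         intensity_cv = intensity_cv, tip_behavior = tip_behavior,
         barrier_pass_prob = barrier_pass_prob, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> D=%g um^2/s, drift=%g um/s, dt=%g s, n=%d, dwell=%g s\n",
    x$D, x$drift_v, x$dt, x$n_particles, x$mean_dwell_s))
  cat(sprintf("  sigma_loc=%g um, capture=%g um, tip=%s, seed=%d\n",
              x$localization_sigma_um, x$capture_radius_um, x$tip_behavior,
              x$seed))
  invisible(x)
}
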
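# Shared fixtures. Configs here silence the step-resolution warning: these
# trajectory runs never resolve encounters, only record positions.

make_cfg <- function(...) {
  sim_config(..., step_rule = "ignore")
}

lambda_sub <- function(...) dna_substrate(...)

lambda_L_um <- 48502 * 0.34 * 0.8 / 1000

# Build a bare trajectory tibble by hand (bypassing the generator) for
# tests that need exact deterministic paths.
manual_traj <- function(times, positions, id = 1L, substrate = NULL) {
  tr <- tibble::tibble(particle_id = id,
                       frame = seq_along(times) - 1L,
                       time_s = times,
                       position_um = positions,
                       intensity_au = 1)
  if (!is.null(substrate)) attr(tr, "substrate") <- substrate
  class(tr) <- c("trajectory_set", class(tr))
  tr
}
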
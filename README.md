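# scanseek

Simulation and analysis of one-dimensional protein scanning and assembly on
stretched DNA.

Innate-immune DNA sensors such as IFI16 must find each other on long foreign
DNA molecules to assemble into signaling oligomers, while being kept off host
chromatin by nucleosomes. Single-molecule experiments address this by tracking
fluorescently labeled protein on flow-stretched λ-DNA (48.5 kbp) and by bulk
FRET and competition-binding assays. `scanseek` provides the computational
side of such a study as a tested, tidyverse-style R package:

- **Synthetic data generation** — Brownian 1D trajectories on a DNA
  coordinate with the Euler–Maruyama update *x ← x + v·dt + √(2D·dt)·ξ*,
  reflecting nucleosome barriers, exponential dwell times, flow drift with a
  sticky free tip, localization noise; kymograph image stacks with Gaussian
  PSF and Poisson shot noise; first-order FRET traces; Hill-form competition
  curves; single-fluorophore cluster intensities
  (`simulate_trajectories()`, `render_kymograph()`, `simulate_fret_trace()`,
  `simulate_competition_curve()`, `simulate_cluster_intensities()`,
  `simulate_cluster_growth()`).
- **Diffusion analysis** — time-averaged mean-square displacement
  MSD(τ) = 2Dτ + 2σ², weighted linear fits in the linear regime, drift
  estimation *v = Σⱼ Δxⱼ / Σⱼ Δtⱼ* and correction, run lengths on
  barrier-laden DNA (`compute_msd()`, `fit_diffusion()`,
  `estimate_diffusion()`, `estimate_drift()`, `correct_drift()`,
  `run_lengths()`).
- **Flow-cell hydrodynamics** — mean flow *v_avg = Q/(h·w)*, the
  plane-Poiseuille profile *v(y) = (3/2)·v_avg·(h·y − y²)/(h²/4)*, and
  wall-corrected Stokes drag *F = 6πηrv·(1 + 9r/(16y))*
  (`mean_flow_velocity()`, `velocity_at_height()`, `stokes_drag()`,
  `hydro_summary()`).
- **Pair-search Monte Carlo** — expected time for two molecules to meet on
  DNA occupied by N molecules in total, simulated on an L/N segment with
  periodic (modulo) distances and a 10-nm capture radius, with a closed-form
  ring first-passage oracle MFPT = ℓ²/(24D) (`simulate_search_time()`,
  `analytic_pair_mfpt()`, `flow_effect()`, `occupancy_sweep()`,
  `dt_convergence_check()`).
- **Cluster stoichiometry** — single-molecule unit intensity, molecule
  counts n = round(I/unit), growth rates and size-dependent mobility,
  colocalization with nucleosome marks (`unit_intensity()`,
  `cluster_sizes()`, `growth_and_mobility()`, `colocalization_fraction()`).
- **Bulk kinetics** — fits of *baseline + amplitude·(1 − e^(−k·t))* and of
  *1/(1 + (c/IC₅₀)^h)*, protomer capacity ⌊length/footprint⌋, and
  rate-versus-length summaries (`fit_first_order()`, `fit_competition()`,
  `protomer_capacity()`, `rate_vs_length_summary()`).

Fitted objects support `tidy()`/`glance()` and every result type has an
`autoplot()` method.

## Worked example

```r
library(scanseek)

# Flow-cell physics at the standard conditions
hydro_summary()
#> # A tibble: 1 × 4
#>   v_avg_cm_per_s v_max_cm_per_s v_y_um_per_s drag_fN
#>            <dbl>          <dbl>        <dbl>   <dbl>
#> 1          0.333            0.5         39.9    1.51

# Simulate 200 tracks at D = 0.026 µm²/s and recover D from MSD fits
cfg <- sim_config(D = 0.026, n_particles = 200, mean_dwell_s = Inf,
                  max_time_s = 5, step_rule = "ignore", seed = 42)
trajs <- simulate_trajectories(cfg, dna_substrate())
ests <- estimate_diffusion(trajs)
median(ests$D_um2_per_s)
#> [1] 0.0261

# Median pair-search time on λ-DNA carrying 50 molecules
mc <- mc_search_config(N_occupancy = 50, n_reps = 500, seed = 42)
glance(simulate_search_time(mc))
#> # A tibble: 1 × 6
#>   median_s mean_s n_reps frac_censored median_flagged segment_um
#>      <dbl>  <dbl>  <int>         <dbl> <lgl>               <dbl>
#> 1    0.055  0.103    500             0 FALSE               0.264
```

The first block says that 0.02 ml/min through a 100 µm × 1 mm channel gives
a 0.33 cm/s mean flow, ~40 µm/s at the 0.2 µm height where the DNA sits,
and ~1.5 fN of drag on a DNA-bound protein — far too weak to strip it off.
The second shows the MSD estimator recovering the generator's diffusion
coefficient (0.026 µm²/s) from 200 noisy tracks. The third gives the median
time (~0.06 s) for two molecules to meet on a λ-DNA molecule shared with 48
others; the mean (0.103 s) is close to the analytic ring first-passage
value for the 0.264 µm segment (0.095 s).

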
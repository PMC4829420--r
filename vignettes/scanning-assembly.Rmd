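---
title: "Models and methods: 1D scanning and assembly on stretched DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: 1D scanning and assembly on stretched DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanseek)
```

`scanseek` implements the computational pipeline of a single-molecule study
of an innate-immune DNA sensor that scans along exposed double-stranded DNA
by 1D diffusion and assembles into oligomeric clusters, with nucleosomes
acting as barriers that keep it off chromatinized (host) DNA. This vignette
is the package's own account of the models it implements, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed. The package is deliberately tidyverse-shaped — data frames
in, tibbles out, `tidy()`/`glance()` on fitted objects, `autoplot()` on
results — because every input and output here is naturally tabular; the
exported functions (plus `scripts/acceptance.R`) are the package's
interface, and no shell wrapper is provided.

## The arena: stretched DNA with point barriers

`dna_substrate()` describes a flow-stretched DNA molecule as a 1D segment.
Lengths convert between base pairs and micrometres with
`nm_per_bp = 0.34 × 0.8` by default: 0.34 nm/bp of B-form contour times a
0.8 extension factor typical of flow-stretched molecules. The extension of
the molecules in the experiments this emulates is not independently known,
so the factor is configurable; all downstream physics depends only on
micrometre coordinates, so this choice rescales the arena without changing
any estimator. λ-DNA (48,502 bp) is the default substrate, giving a
stretched length of about 13.2 µm.

Nucleosomes are modelled as *point* barriers at their dyad positions.
Observed motion is confinement between obstacles, but a per-encounter pass
probability is not measurable from the data this package emulates, so
barriers are perfectly reflecting by default with a configurable
`barrier_pass_prob` (0–1) for sensitivity analyses. When a step would cross
a leaky barrier, at most one barrier interaction per step is resolved —
adequate because steps are small compared with barrier spacing.

Anchoring matters: double-tethered molecules are imaged without flow (no
drift), while single-tethered molecules are stretched by flow, acquire a
drift velocity, and have a free downstream tip. A particle reaching the tip
sticks there by default (`tip_behavior = "stick"`), matching the
observation that molecules ride the flow to the free end and accumulate;
`"unbind"` ends the track instead.

## The trajectory generator

`simulate_trajectories()` integrates the overdamped Langevin dynamics with
the Euler–Maruyama update

x ← x + v·dt + √(2·D·dt)·ξ,  ξ ~ N(0, 1),

with reflection at segment boundaries, binding positions uniform on the
DNA, exponential dwell times (mean `mean_dwell_s`, default 10 s — bound
lifetimes of seconds to tens of seconds are typical here), and i.i.d.
Gaussian localization noise (σ = 0.03 µm by default, a routine
single-fluorophore localization precision) added *post hoc* to the recorded
positions, so the dynamics are exact and the noise enters only the
measurement. Default D = 0.026 µm²/s, the no-flow single-molecule value
this pipeline is organized around, and drift v = 0.127 µm/s when flow is
on. Where there is no drift, no leaky barrier and no absorbing tip, the
generator uses the exact folding identity (a reflected path is the
triangular fold of the free path), which vectorizes the whole track;
otherwise it steps through time.

Reproducibility is strict: a master stream is seeded from the mandatory
config seed and per-particle sub-seeds are drawn from it, so a trajectory
set is reproducible bit for bit.

**The step-resolution rule.** Encounter-based simulations must resolve the
capture radius: `sqrt(2·D·dt) + v·dt < capture_radius`. The pair-search
configuration (`mc_search_config()`) enforces this as an error, and its
default `dt = 0.001 s` is the largest round value satisfying the rule at
D = 0.026 µm²/s and the 10-nm capture radius. The trajectory generator, by
contrast, records positions at the imaging frame interval (default
`dt = 0.01 s`, a typical EMCCD exposure) and never resolves encounters, so
there the rule is a warning by default (`step_rule` can escalate it to an
error). Exposure time, pixel size and localization precision of the
emulated microscope are declared defaults, not inferred quantities.

**Kymographs.** `render_kymograph()` converts trajectories to synthetic
raw data: per frame, each particle contributes a Gaussian PSF profile
integrated exactly over pixels (so total signal is conserved), profiles are
summed with a uniform background expectation, and Poisson shot noise is
applied. This is an intensity model only — photobleaching steps, blinking,
camera EM gain and readout noise are deliberately not modelled.

**What the generator does not emulate.** Motion is strictly 1D (no 3D
excursions or hopping between DNA segments), the DNA is a static
coordinate (no polymer fluctuations), binding is sequence-independent, and
intensities are Gaussian-per-fluorophore sums (no photophysics). Tests
that pass on these synthetics therefore validate the *estimators and the
simulation physics they assume*, not the full complexity of real
microscopy data.

## MSD analysis and drift

`compute_msd()` computes the per-molecule, time-averaged MSD over all
overlapping ordered pairs at each lag (a non-overlapping option exists,
and `compute_msd_ensemble()` provides the ensemble average; whether a
per-molecule or ensemble average is the better headline is data-dependent,
and the per-molecule time average is the default because per-track D
values are what the downstream median summarizes). Sampling must be
uniform to 1%; irregular tracks are rejected with advice to resample
rather than silently interpolated.

`fit_diffusion()` fits `msd = 2·D·τ + b` by least squares weighted with
the number of pairs per lag. The intercept absorbs the static localization
error (2σ², ≈ 0.0018 µm² at the default σ), which is why the offset is
fitted rather than forced through zero. The "linear regime" is chosen
automatically: start at lags 2–10 and shrink the upper end until weighted
R² ≥ 0.9 or three points remain. Lag 1 is excluded as the lag most
distorted by noise correlations; ten lags keeps the window well inside the
unconfined regime for the track lengths used here. Negative fitted slopes
(noise-dominated tracks) are clipped to D = 0 and flagged, not discarded —
discarding them would bias the per-condition median upward. The median,
not the mean, is the headline per-condition D, because per-track MSD
estimates are heavy-tailed.

`estimate_drift()` implements v = Σⱼ(x_final − x_initial) / Σⱼ(t_final −
t_initial) over all trajectories: net displacements divided by total
elapsed time, signed along the flow. (The formula's denominator is read as
total elapsed time; the estimator is then the maximum-likelihood drift for
Brownian motion with a common drift.) `correct_drift()` subtracts
v·(t − t₀) per track. `run_lengths()` reports each particle's net travel
distance from binding to tip arrival or unbinding; on barrier-laden DNA,
reflecting barriers cap these at the enclosing segment width, which is the
mechanism behind the stochastically shorter run lengths on nucleosomal
DNA. Dwell-time analysis is exposed only as raw summaries
(`dwell_summary()`); no parametric dwell model is fitted because the
acquisition window censors long dwells.

## Flow-cell hydrodynamics

All hydrodynamics are evaluated in SI internally with unit conversion at
the interface, and reproduce the standard worked values at two significant
figures: Q = 0.02 ml/min through a 100 µm × 1 mm channel gives
v_avg = Q/(h·w) = 0.33 cm/s; the plane-Poiseuille profile
v(y) = (3/2)·v_avg·(h·y − y²)/(h²/4) gives ≈ 40 µm/s at y = 0.2 µm, the
average height of surface-tethered DNA; and the wall-corrected Stokes drag
F = 6πηrv·(1 + 9r/(16y)) gives ≈ 1.5 fN. The hydrodynamic radius behind
that drag value is not independently documented; r = 2 nm reproduces it
and is therefore the package default, explicitly flagged as an inference.
Finite-width corrections to the parabolic profile are neglected — the
channel's 10:1 aspect ratio makes them irrelevant at the precision quoted
— and the profile integrates back to v_avg to machine precision (a
quadrature identity the tests check). No tether mechanics (worm-like
chain) are modelled.

## The pair-search Monte Carlo

The central stochastic model: how long do two molecules need to find each
other on a DNA molecule occupied by N molecules in total? Since all
particles are equivalent, the DNA is segmented into N stretches of length
L/N and one pair is simulated on a segment with periodic boundaries; the
separation is the absolute distance modulo the segment length, folded to
the shorter arc. Capture occurs at separation ≤ 10 nm (the distance at
which two molecules are considered met and dimerized). Segmentation is
implemented literally as stated — the pair does not interact with the
other N − 2 walkers beyond the segment geometry they impose.

Design choices:

- **Gaussian increments**, not lattice steps: a "random walk" with
  Gaussian steps reproduces the target diffusion coefficient exactly at
  any dt.
- **Drift advects both walkers** (`advection = "common"`), the literal
  reading of adding v·dt to each random step. The pair separation is then
  independent of drift, so with matched seeds the capture times are
  *identical* at any drift — the package's strongest statement of why flow
  does not alter the search time. A `"single"`-walker variant is provided
  for sensitivity analysis; there drift does accelerate capture.
- **Censoring** at `max_time_s` is explicit: censored replicates carry a
  flag, the median is computed on uncensored times and flagged unreliable
  above 50% censoring, and above 90% the run errors with advice to extend
  the horizon.
- **Replicates**: 2000 by default, which resolves median ratios at the few
  percent level; the tests use between 200 and 2000 depending on how sharp
  the assertion is.

The independent oracle is the closed-form ring first-passage time: the
relative coordinate diffuses with 2D on a ring of circumference ℓ, so the
mean first-passage time from a uniform start is ℓ²/(24·D), with a finite
capture radius handled as an effective circumference ℓ − 2a (an O(a/ℓ)
approximation of the exact (ℓ − 2a)³/(24·D·ℓ), noted in the
documentation). `occupancy_sweep()` exposes the resulting (L/N)² scaling:
doubling N roughly quarters the median search time — the quantitative
reason crowding *accelerates* assembly.

**Time-step convergence.** Comparing independent runs at dt and dt/2
confounds the discretization effect with Monte-Carlo noise, so
`dt_convergence_check()` uses a matched-path comparison instead: the walk
is simulated at dt/2, and because Gaussian increments compose exactly, the
same paths observed at every other step are a faithful dt-step
simulation. Checking capture at every step versus every other step on the
same paths isolates the pure effect of halving dt with the path
randomness cancelled; at the defaults the median moves by about a percent.

## Cluster stoichiometry and growth

`unit_intensity()` calibrates the single-fluorophore unit as the median
(reported with its MAD) of the singles distribution — robust against the
bright tail that undetected doubles create — and warns when a 1- versus
2-component Gaussian mixture comparison (BIC margin > 10) indicates a
bimodal singles population. `cluster_sizes()` rounds intensity/unit to the
nearest integer (rounding, not flooring: with a symmetric unit
distribution, flooring would bias every count down by half a molecule on
average) and floors at one molecule. Counts are invariant under joint
rescaling of intensities and unit. No correction for partial labeling is
applied: reported sizes are labeled-molecule counts, i.e. lower bounds on
true stoichiometry.

`simulate_cluster_growth()` emulates time-resolved clustering: Poisson
molecule additions at a rate independent of current size by default (the
non-cooperative mechanism; `rate_size_exponent` makes growth
size-promoted for sensitivity analyses) and mobility decaying as
D_mono·n^(−1), so clusters slow as they grow. `growth_and_mobility()`
estimates per-cluster addition rates (slope of n(t)), tests
rate-versus-size association by Spearman rank correlation, summarizes
median D per size bin, and flags clusters with D < 10⁻³ µm²/s as immobile
— an order of magnitude below typical single-molecule mobility here, so
the flag is insensitive to fit noise. `colocalization_fraction()` uses a
0.2 µm default threshold (≈ the diffraction limit); for uniform marks at
density ρ the expected chance fraction is 1 − exp(−2ρ·threshold), the
closed form used to test it.

## Bulk kinetics and competition fits

`fit_first_order()` fits baseline + amplitude·(1 − e^(−k·t)) by
Levenberg–Marquardt. Initialization is from the data (baseline from the
minimum, amplitude from the rise, k₀ = 1/t_half from the half-rise time)
and k is bounded to [0, 10/t_max] — a rate faster than that is not
resolvable on the trace's time base. Mixing dead time (typically 15–20 s
in plate-reader assays) is handled by the `dead_time` argument shifting
the time origin (the package does not pick a default dead time; traces
simulated without one fit with `dead_time = 0`). Constant traces return
k = 0 flagged rather than erroring, since a zero-amplitude trace is a
legitimate "no assembly" observation. `protomer_capacity()` encodes the
⌊length/footprint⌋ gate with the 15-bp footprint: 60 bp → 4 copies (the
initiation threshold), 150 bp → 10 (the optimal oligomer), < 15 bp → 0.
`rate_vs_length_summary()` flags saturation where successive rates differ
by under 10%.

`fit_competition()` fits 1/(1 + (c/IC₅₀)^h) to fraction-bound data,
normalized to the zero-competitor plateau (raw anisotropy scales vary
between experiments; the zero-competitor point is the natural internal
reference). The fit is equivariant under concentration rescaling — IC₅₀
scales, the Hill coefficient does not — which the tests assert exactly. A
curve that declines but never crosses 0.5 is fitted with a wide-CI
warning; a completely flat curve is rejected as unidentifiable.

## Numerical and testing choices

Problem sizes in the test suite are chosen so the full suite runs in well
under a minute while keeping the statistical assertions sharp: 100-seed
sweeps for fit recovery (k recovered within 10% at every seed; IC₅₀/Hill
judged by the sweep median, since a single 12-point titration at 2% noise
carries irreducible per-seed scatter of several percent), 500 tracks for
diffusion and drift recovery, 2000 replicates for search-time medians, 150+
tracks per arm for the barrier run-length rank test (α = 0.01). Stochastic
tests fix their seeds; tolerance bands are derived from closed forms
(standard errors, Poisson/binomial counting, the ring MFPT) rather than
from observed spreads.

## Known limitations

- Barriers are points with all-or-nothing reflection; real nucleosomes
  have footprints, breathing dynamics and partial passage.
- The MSD estimator suite is deliberately minimal: no covariance-based or
  maximum-likelihood D estimators, no state segmentation, no
  anomalous-diffusion exponents.
- The pair-search model reduces the many-body problem to a segmented pair
  and so cannot capture occupancy fluctuations or cluster-mediated
  captures.
- Bulk fits operate on raw trace units; per-well normalization choices in
  plate-reader data are left to the user.
- Labeled-molecule counts understate true cluster stoichiometry when
  labeling is incomplete.
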
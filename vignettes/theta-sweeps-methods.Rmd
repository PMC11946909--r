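---
title: "Models and methods behind thetasweeps"
author: "thetasweeps authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetasweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`thetasweeps` studies a single phenomenon: within each cycle of the 5–10 Hz
theta rhythm, the position represented by entorhinal–hippocampal population
activity "sweeps" outward from the animal along a near-linear path, and the
direction of successive sweeps alternates left–right about the head axis.
The package provides everything needed to reproduce that analysis chain on
synthetic data: a generative model of spatially and directionally tuned
spike trains carrying latent sweep structure, preprocessing (binning, rate
maps, theta phase, cell classification, sleep staging), population decoders,
per-cycle sweep extraction with alternation statistics, cross-correlogram
connectivity detection, a Poisson GLM with a theta-phase-dependent position
shift, and an ideal overlap-minimizing sweep-generating agent.

All quantities of interest are computed by the package itself; this
vignette explains the models, the tunable parameters, and the numerical
decisions, so that each default is interpretable rather than magic.

# The synthetic session generator

The generator defines the study conditions every downstream stage assumes.

* **Trajectory** (`generateTrajectory()`): a correlated random walk in a
  150 × 150 cm arena with an Ornstein–Uhlenbeck speed process (mean
  24 cm/s, SD 8 cm/s) and Gaussian heading diffusion (1.6 rad/√s),
  reflected at the walls. These values emulate vigorous open-field foraging
  and give ≥ 80 % coverage of 2.5 cm bins within 600 s; head direction is
  identified with movement direction.
* **Theta** (`generateTheta()`): cycles at 8 Hz with 5 % lognormal
  cycle-length jitter, so cycle detection downstream is non-trivial. Phase
  runs linearly 0 → 2π within a cycle; phase 0 is the population-activity
  minimum by construction (cells' preferred phases centre on 180°).
* **Latent sweeps** (`generateLatentSweeps()`): each cycle receives an
  internal direction equal to the heading ± 30°, alternating across cycles
  (or an iid fair coin when alternation is off). Within a cycle the
  represented position ramps linearly in phase from 5 cm *behind* the
  animal to up to 35 cm out along the internal direction — the
  "starts slightly behind, sweeps outward" geometry seen in decoded data.
* **Tuning models**: grid cells are hexagonal lattices of Gaussian bumps
  (default spacing 75 cm or a √2-spaced pair of modules; field width
  σ = spacing/6; peak rate lognormal around 30 Hz); internal-direction
  cells are von Mises bumps (κ = 6); every cell carries a multiplicative
  von Mises theta-phase gain with per-cell preferred phases dispersed
  around 180° (SD 0.8 rad). The dispersion matters: a population whose
  cells all share one preferred phase produces a *line*, not a circle, in
  the PC1–PC2 plane, and the population phase estimator would fail — as it
  would on no real population.
* **Spiking**: per-bin Poisson counts at rate(tuning at latent position /
  internal direction) × phase gain, 10 ms bins.

A note on one printed simulation parameter: the source simulation of a
single grid cell quotes a field width of "σ = 0.5 cm" at 75 cm spacing,
which is geometrically implausible (fields narrower than a rat's paw);
`gridCellModel()` therefore defaults to σ = spacing/6 and exposes `sigma`
for any override.

What the generator does *not* emulate: conjunctive phase precession
mechanisms beyond what sweeps induce, bursting at the membrane level,
non-Poisson spike-count dispersion, slow drift of tuning, or
multi-animal variability. Tests passing on these sessions demonstrate the
*pipeline's* correctness under the stated model, not the biology of any
particular animal.

# Preprocessing choices

* **Speed filters**: 5 cm/s for generic spatial analyses, 15 cm/s for sweep
  statistics (alternation is a running phenomenon).
* **Cross-validated smoothing**: rate maps are smoothed with the Gaussian
  width minimizing 10-fold prediction MSE, the folds being contiguous
  equal-duration blocks; the search uses `optimize()` on (1, 50) cm or
  (0.01, 1) rad. Decoder reference maps instead use fixed widths (7.5 cm
  spatial, 12° angular) so that decoding is not entangled with the CV
  machinery.
* **Theta phase**: 2nd-order zero-phase Butterworth (5–10 Hz) on per-cell
  counts, PCA across cells, phase = angle in the PC1–PC2 plane, rotated so
  the population-activity minimum sits at phase 0 and phase advances in
  time.
* **Grid modules**: coarse 10 cm unsmoothed maps → spatial
  autocorrelograms → Manhattan 30-NN graph → Leiden clustering
  (modularity objective, resolution 1.0). A cluster is a module if the
  grid score of its median autocorrelogram exceeds 0.3, median member
  consistency exceeds 0.5 and it has ≥ 10 cells; clusters correlating
  above 0.7 merge first. The grid score itself is the standard rotational
  annulus score (min of 60°/120° correlations minus max of 30°/90°/150°),
  with the annulus inner radius at the first drop of the radial profile
  below 0.2 and the outer radius scanned; only threshold behaviour is
  asserted in tests, since the literature's annulus conventions vary.
* **Sleep staging**: immobility > 120 s; theta/delta Hilbert-envelope
  ratio of the summed binarized population rate (4th-order Butterworth,
  Gaussian σ = 5 s smoothing); ≥ 20 s above 5.0 → REM, below 2.0 → SWS.
  The ratio is taken on the smoothed envelopes directly: a ratio of
  z-scores is numerically ill-defined near zero and would make the
  thresholds arbitrary.

# Decoding

The PV decoder Pearson-correlates each 10 ms population vector (counts
smoothed with σ = 10 ms) against mean-normalized reference PVs at every
2.5 cm bin; the argmax is the decoded position and the trajectory is
smoothed with σ = 8 ms. Bins are kept only when at least five cells fired
and the peak correlation exceeds the 99th percentile of a null built by
permuting cell identities of the map stack (100 draws — the shuffle count
is unstated in the source; 100 gives the 99th percentile ~1 % Monte-Carlo
error on the pooled sample, and the calibration test verifies ≤ ~1 % of
label-shuffled bins pass). Argmax ties take the earliest bin,
deterministically, with a tie flag.

The Bayesian decoder inverts Poisson likelihoods with a flat prior, tuning
curves floored at 0.01 Hz to avoid log 0. It consumes the same smoothed
firing rates as the PV decoder (times dt), which is what makes the
cross-decoder consistency criterion (MAP within one bin of the PV argmax
for ≥ 90 % of valid bins) an apples-to-apples comparison. That criterion
is evaluated on a 5 cm decoding grid: a single 10 ms population vector
carries ~2.3 cm of intrinsic decoding noise for *each* decoder, so on a
2.5 cm grid two near-identical estimators would disagree by more than a
bin ~25 % of the time no matter how sharp the tuning — bin-level agreement
is a meaningful consistency statement only when one bin covers the
single-decoder noise scale. The 2.5 cm grid remains the default
everywhere else.

The lowpass reference trajectory decodes wide-smoothed (σ = 1.7 cycles)
counts from each cycle's first half; it anchors sweep vectors. Internal
direction is decoded per cycle at the bin of maximal population activity as
the correlation-weighted circular mean over the 60 angular bins. The
unsupervised PCA readout bins counts per theta cycle (so global
within-cycle rate fluctuations cannot dominate), takes the PC1–PC2 angle,
resolves the arbitrary rotation *and chirality* by aligning against head
direction, and assumes equal mean internal and head direction.

Single-module decoding cross-correlates the PV-correlation map with the
module's template (mean autocorrelogram trimmed to the central peak plus
first ring — farther lattice orders add no alignment information on an
arena-sized map and only contribute edge artefacts); the peak nearest the
origin, expressed in the basis of the two shortest lattice vectors, gives
the toroidal phase.

# Sweeps and alternation

Sweep candidates are the longest run of consecutive valid bins with jumps
< 20 cm and bearing changes < 90°, truncated to the contiguous subsequence
maximizing net displacement (exact O(k²) search), anchored at the lowpass
position at cycle start, and kept when ≥ 4 samples and axis r² > 0.5.
Bearings of displacements under 1 cm (below decoder resolution) are
treated as uninformative rather than as turns. Triplet alternation is
"opposite signs of successive circularly wrapped direction changes", which
reproduces the 2/3 iid chance rate; the side-of-head-axis reading is not
used. Previous-side conditioning skips sweep-less cycles (most recent
detected sweep). The three-sweep alternation score wraps both the
successive differences and their difference to (−π, π] before evaluating
|a − b| / (2 max(|a|, |b|)); without the outer wrap the chance level would
be 0.5 rather than the 0.40 the score is designed around.

One chance level deserves care. For iid *uniform* directions on the
circle, wrapped successive differences are mutually independent, so the
triplet sign-inversion rate is exactly 1/2 — not the 2/3 familiar from
linear iid sequences. The 2/3 rate re-emerges as soon as the direction
distribution is concentrated (e.g. the ±30° bimodal decoded data), where
wrapping is immaterial and the order-statistics argument applies; that is
also why shuffled *empirical* direction sequences sit near 0.61 rather
than at either idealized value. The tests assert both regimes against
Monte-Carlo oracles.

# Connectivity

CCGs use 1 ms bins over ±50 ms with a hollowed-Gaussian baseline (σ = 5 ms,
hollow fraction 60 %, reflected edges). A connection requires the
baseline-corrected peak to fall in 0.7–4.7 ms, exceed five SDs (SD over all
bins excluding the peak), have Poisson P < 0.001 with continuity
correction, width < 3 ms, and not touch lag 0; candidates are discarded on
any non-peak bin above 2.5 SD or on P < 0.01 in the *mirrored anticausal
window* (−4.7 to −0.7 ms). Applying the anticausal guard to all fifty
anticausal bins instead would reject ~40 % of genuine connections on noise
alone, which no calibrated detector could tolerate; the mirror window is
the common-input guard used by the established CCG pipelines.

# The shift GLM

Counts are modelled as Poisson with log-rate linear in basis-expanded
covariates: 2D Gaussian position basis (σ = 2 cm on a 10 cm triangular
grid, with a 40 cm buffer beyond the walls so fields may extend outside
the arena), and 50 von Mises functions (κ = 10) for head direction,
internal direction and theta phase. Each block is PCA-reduced (99 %
variance for position, 80 % for angular blocks). The sweep correction
shifts the position covariate by δ(θ) = γ₀ + γ·X_θ along the per-bin
internal direction; β and γ are optimized by alternating convex β steps
with BFGS γ steps until the log-likelihood gain falls below 1e-6 (at most
12 outer iterations, divergence falling back to γ = 0). The γ gradient is
evaluated analytically by the chain rule through the shifted Gaussian
basis — mathematically identical to a finite-difference gradient but an
order of magnitude cheaper, which is what makes single-cell fits run in
about a minute at the problem sizes used here (150–200 s sessions,
~50-dimensional retained position blocks). δ(θ) is unconstrained in sign,
so backward shifts at early phases are representable.

# The sweep-generating agent

The footprint is f(**x**) = 1/d² · exp(κ cos(θ − α)) with κ = 5; the
coverage trace h accumulates past footprints (decayed by τ^dt in
trajectory mode); the chosen direction minimizes Σ f(x, α) h(x) over a 1°
angle grid, exact ties broken by a seeded uniform draw.

Two numerical points deserve emphasis.

* **Overlap evaluation.** exp(κ cos(θ − α)) is expanded in a Jacobi–Anger
  Bessel series (12 harmonics, truncation error ~1e-8), so one pass over
  the grid yields the whole overlap curve. Inside the production linear
  run, trace cells beyond 48 bins of the agent are aggregated into 4 × 4
  blocks; the far field carries only ~1/d³ of the overlap mass, and the
  block approximation stays well below the 1° argmin resolution (the
  exported `overlapCurve()` remains exact, and tests compare the two).
* **Near-field regularization.** The continuum overlap integral diverges
  logarithmically at the footprint origin, but its divergent part is
  direction-independent; only the regularization's *anisotropy* can move
  the argmin. Point-sampling 1/d² at cell centres with just the origin
  cell masked is therefore pathological: the four d = 1 cells carry weight
  e^±κ with square symmetry, and the emergent sweep angle then flips with
  the parity of the step length in bins. The package instead masks a disk
  of radius 1.5 bins and integrates cells within 12 bins by 5 × 5
  sub-cell averaging, restoring the near-ring isotropy of the continuum
  field. Under this regularization the straight-path behaviour is robust
  to step length and sub-bin start offsets, and the published alternation
  regime (two modes ~33° off the movement axis, near-perfect late-run
  alternation) emerges without tuning any footprint parameter.

The straight-path simulation uses the 401 × 401 scale-free grid, a step of
5 bins, 30 steps per run, uniformly random first directions and sub-bin
start jitter as the random initial conditions, and evaluates "late-run"
quantities over the final 10 steps, where the sliding-window score has
plateaued (the source does not print its run length). Trajectory mode maps
the arena onto 1 cm bins at the grid centre, yokes steps to theta cycles,
and defaults to τ = 0.04/s (trace intensity halves every 215 ms). The
multimodule variant uses three Gaussian-blob footprints with geometric
ratio 1.5 under common, parallel or serial updating.

# Problem sizes and determinism

The test-suite sessions are deliberately compact: 30–150 s sessions for
unit tests; an 80 s, 450-grid-cell session for the end-to-end sweep
recovery benchmark (the ≥ 300-cell condition of that benchmark, at the
cell yields typical of large entorhinal recordings); 10,000 independent
Poisson pairs for detector calibration; 1,000 agent runs for the
simulation statistics. Every stochastic step takes an explicit seed, and
the pipeline is bit-reproducible for a fixed configuration.

# Known limitations

* The generator's sweeps ramp linearly in phase; real sweeps compress into
  the late half of the cycle, so decoded sweep lengths here are mildly
  conservative.
* The PCA direction readout assumes the internal-direction distribution is
  symmetric enough that its mean matches head direction; a session spent
  turning one way would bias the alignment.
* Sleep staging is a two-band amplitude-ratio classifier; it does not
  model micro-arousals or transitional states, and flat segments with
  neither band default toward SWS.
* The toroidal decoder needs the template's first lattice ring to fit
  inside the arena (spacing ≲ arena/2); larger-spacing modules fall back
  to essentially single-peak matching.
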
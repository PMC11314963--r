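---
title: "Methods: e-nose volatilome classification and GC-MS profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-nose volatilome classification and GC-MS profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voclass)
```

## The measurement model

A metal-oxide (MOX) gas sensor is a heated semiconducting film whose
electrical resistance changes when volatile compounds react at its
surface. For n-type layers (SnO2, here pure or doped with Pd or Au)
exposed to reducing volatiles, the resistance *drops*; the size and shape
of the drop depend on the sensing layer and on the gas mixture, so an
array of six differently doped sensors yields a six-dimensional
fingerprint of a sample's headspace.

One measurement cycle follows a fixed schedule: 100 s of stabilization
under filtered air, 200 s of analysis while the sample headspace flows
over the array, and 500 s of recovery, sampled at 1 Hz by default (800
points). The nominal cycle length quoted for the instrument workflow is
13 minutes; the three phases sum to 800 s (13.3 min). We treat the phase
durations as the operative definition and keep `cycle_minutes = 13` as
design metadata only — it enters nothing but the session-length
bookkeeping, where the instrument's own nominal figure is the right one
(10 replicates in 130 min).

### The synthetic trace generator

No public repository of raw recordings exists for this kind of
experiment, so the package ships a generator whose defaults *are* the
study conditions, and all tests run against it:

- **Kinetics.** First-order exponential response and recovery:
  during analysis the resistance decays toward
  `baseline * (1 - amplitude)` with the sensor's response time constant
  (15–25 s across the array), and recovers toward baseline with a slower
  constant (65–90 s) — the simplest model consistent with the monotone
  drop-and-recover shape of real recordings. A zero time constant gives a
  step response, which makes several closed-form tests exact.
- **Class structure.** A response matrix assigns each (sensor, class)
  pair a fractional amplitude. Sensor base amplitudes are
  doping-dependent (0.32–0.55); cooking adds a sensor-specific shift of
  0.06–0.15 (cooked meat releases more volatiles); each diet adds a
  ±0.05 six-sensor fingerprint. A `separation` factor scales both class
  effects: 0 collapses all classes, 1 is the default condition.
- **Noise.** Multiplicative log-normal with relative SD 0.01 (about 1%
  cycle-to-cycle resistance jitter, a realistic figure for a conditioned
  MOX array in a temperature-controlled chamber) plus a linear baseline
  drift of 2e-5 per second (±1.6% over a cycle). Resistance is positive
  and spans decades across sensors, which is why the noise is
  multiplicative rather than additive.
- **Design.** 48 samples (8 classes × 6), triplicate GC-MS analyses and
  10 e-nose cycles per sample — 624 analyses in total.

What the generator does *not* emulate: humidity and temperature
covariates, sensor aging and drift across sessions, carry-over between
consecutive cycles, and bird-level biological structure (the design is
sample-level; pen/bird hierarchies are out of scope). Passing tests
therefore demonstrate that the pipeline recovers class structure that is
present in the traces, not that real poultry data are this clean.

## Signal processing

Normalization divides each trace by R0, defined as the **mean resistance
over the stabilization phase** rather than the literal first sample; the
phase mean is robust to single-sample noise and agrees with the first
sample exactly in the noiseless case. Segmentation assigns samples to
phases by time stamp with half-open windows (`[0, t1)`, `[t1, t2)`,
`[t2, end]`), so the three index sets partition the trace exactly;
recordings that run past the schedule put their trailing samples in
recovery, and recordings shorter than the schedule are rejected. The
per-sensor response summary is `ΔR = 1 − min(R/R0)` over the analysis
phase. No smoothing or drift correction is applied anywhere — features
see the trace as recorded.

Two distinct "ΔR" conventions coexist deliberately: the signal-level
summary above (drop from baseline to the analysis minimum), and the
feature-table `delta_r` (max − min excursion of the whole track). Both
are implemented and kept apart.

## The feature set

Eleven descriptors per sensor, 66 per cycle, computed on the normalized
(R/R0) trace so arrays with different absolute baselines are comparable:

| feature | definition | interval |
|---|---|---|
| `sharpe_fwd_25`, `sharpe_fwd_50` | mean/SD of the leading 25% / 50% window | full track |
| `sharpe_back_25`, `sharpe_back_50` | mean/SD of the trailing window | full track |
| `min_derivative`, `max_derivative` | extrema of finite differences dv/dt | analysis |
| `integral` | trapezoidal area | analysis |
| `delta_r` | max − min excursion | full track |
| `log_sum` | Σ ln(values) | full track |
| `minimum`, `maximum` | track extrema | full track |

Numerical conventions, each of which was a genuinely open choice:

- **Windows** hold `ceiling(fraction × n)` points (never empty), and the
  SD is the sample (n−1) SD, conventional for small windows. A zero-SD
  window makes the ratio undefined; the extractor substitutes a sentinel
  (default 0) with a warning instead of propagating NaN into the
  classifier.
- **"Selected interval."** The derivative and integral features are
  computed on the analysis phase, where the gas interaction happens; the
  interval is the *closed* time window `[t1, t1 + 200 s]`, including the
  boundary sample at the start of recovery when one exists, so the
  integration span equals the scheduled analysis duration (a constant
  unit trace integrates to exactly 200). An `interval = "full"` policy
  switch computes both on the whole track instead.
- **`log_sum`** is the sum of natural logarithms Σ ln(xᵢ) — well defined
  because normalized resistances are positive — with ln(Σxᵢ) available
  behind `log_sum_mode = "log_sum"`.
- The full 66-feature set is the default input to classification; a
  ΔR-only analysis is available by summarizing cycles with
  `cycle_summary()` instead.

## Discriminant analysis

For k classes the fit computes the within-class scatter S_w and
between-class scatter S_b and takes the leading eigenvectors of
S_w⁻¹ S_b as the discriminant basis — at most k − 1 axes, since S_b has
rank at most k − 1. With 66 features and a few dozen training cycles,
S_w is singular or ill-conditioned, so it is shrunk toward its diagonal:
S_w(s) = (1 − s) S_w + s·diag(S_w), default s = 0.1. The default is the
smallest round value that keeps the solve well-posed at the study's
sample sizes while perturbing the well-conditioned two-class geometry
negligibly (the Fisher-direction oracle still holds to cosine ≥ 0.999 at
s = 0). Shrinkage 0 with singular scatter fails loudly with a
remediation hint rather than silently pseudo-inverting.

Determinism details: eigenvector signs are fixed (largest-magnitude
component positive) so projections are reproducible; posterior ties are
broken by class order. Priors are the training class frequencies.
Prediction uses Gaussian class-conditionals with the shared projected
covariance S_w(s)/(n − k) in discriminant space.

The holdout protocol is a stratified 80/20 split with per-class test
count `ceiling(0.2 × n_c)` — ceiling is the only rounding rule consistent
with both published split sizes this mirrors (46 of 228, 42 of 209) —
capped so every training class keeps at least one member. Stratification
is not strictly part of the published protocol but prevents empty-class
test folds at small n; the split is seeded and reported. Test accuracy
is the headline number; training accuracy is logged alongside because
published accuracy figures of this kind often do not state which set
they refer to.

## Evaluation conventions

- **Confusion matrices** are row-normalized (true-class percentages):
  "62% of class A was classified as B" reads along a row.
- **ROC curves** sweep thresholds over the unique scores in descending
  order with ties grouped. The AUC is the trapezoidal area; an
  independent pair-counting (Mann–Whitney) implementation with half
  credit for ties ships alongside, and the two must agree to 1e−12 —
  a dual-route invariant the test suite enforces on a thousand random
  problems.
- **Micro averaging** pools all (class indicator, class score) pairs into
  one binary problem; **macro AUC** is the unweighted mean of class AUCs,
  with the macro curve drawn by mean-TPR interpolation on the union FPR
  grid and re-anchored at (0, 0). The macro *curve* is for display; the
  macro AUC is defined by the mean, not by the interpolated curve's area.
- The chance baseline in ROC panels is the diagonal.

## GC-MS profiling

Peak filtering retains areas **not less than** the threshold (boundary
inclusive, default 500); a surviving-peak count below 70 raises a QC
warning but keeps the table, because small synthetic tables are
legitimate by design. Relative abundance is 100 × area / Σ area over the
retained peaks. Replicate aggregation matches compounds by exact name
(library identity matching is out of scope), counts a compound absent
from a replicate as 0% there — required for mean ± SD to be well defined
— with present-only averaging behind `absent_as_zero = FALSE`. State
comparison reports per-chemical-class compound-count and mean-abundance
deltas plus state-exclusive compound lists.

The synthetic compound library (20 compounds, 8 chemical classes) encodes
the qualitative structure expected of poultry volatilomes: hexanal
dominant among aldehydes, 1-octen-3-ol the leading alcohol, cooking
scaling aldehydes/alcohols/ketones up and carboxylic acids down, with
small diet-specific modifiers (e.g. elevated ketones in the cooked
sustainable-diet class). Compound-level abundances are otherwise
invented plumbing: no numeric compound-level claim is made beyond what
the generator plants.

## Test problem sizes and the recovery property

The parameter-recovery test simulates four cooked-diet classes at 3
samples × 10 cycles each (120 cycles), over 10 seeds, at separations
{0, 0.01, 1}: accuracy must sit within the binomial 99% CI of chance
(25%) at 0, strictly between chance and perfect at 0.01, and at 100% at
1, monotone across the grid. The low point is set where the
between-class amplitude gap (0.05 × separation per sensor) meets the
noise floor of the window-averaged features (≈ σ/√n_analysis ≈ 7e−4),
which is the regime in which a classifier is informative but imperfect.
These sizes keep the whole suite under a minute while leaving the
binomial bounds tight enough to be meaningful; the acceptance script
uses the full default design (24 samples × 10 cycles per state).

## Known limitations

- The trace model is single-compartment first-order; real MOX responses
  show multi-exponential tails, humidity sensitivity and session drift.
- Compound identification, retention-index calibration and spectral
  library matching are out of scope; compounds are matched by name.
- The discriminant model assumes shared within-class covariance;
  strongly heteroscedastic classes would call for quadratic variants,
  which are deliberately not provided.
- With default separation the synthetic problem is easy (accuracy 100%);
  the generator is a test bed for the pipeline's correctness, not a
  difficulty benchmark.
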
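---
title: "qdtrack methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qdtrack methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdtrack)
```

This vignette is the package's account of its science: the motion model
behind the synthetic-data generator, the estimators that make up the
analysis, the parameters that matter and their defaults, the numerical
choices at the edges, and the known limitations — in particular two
estimator biases that the validation studies expose deliberately.

## The measurement setting

The package targets single-particle tracking of quantum-dot (QD) labeled
endocytic cargo in live cells: epifluorescence movies at 10 Hz
(`dt = 0.1` s/frame), 267 nm pixels, and a localization precision of
10–30 nm per coordinate. Upstream detection and linking (e.g. the ImageJ
Particle Tracker) are out of scope; the package ingests the tracker's
text output or a plain trajectory CSV, removes tracks of 50 frames or
fewer (too short for windowed MSD statistics), and analyzes what
remains. Positions are micrometres in the image convention (origin
top-left, y increasing downward, 0-based frames).

## Motion model and synthetic-data generator

No public tracking data accompany this problem class, so the generator
is a first-class, tested component: it defines the study conditions
under which every estimator is validated.

Each trajectory follows a first-order Markov chain over three motion
states, one state per frame step:

- **Constrained** (near immobility): a discrete Ornstein–Uhlenbeck walk
  around a stint anchor with stationary standard deviation
  `confinement_radius / 2` per coordinate and relaxation time
  `(confinement_radius / 2)^2 / D_free`. The default radius, 0.05 µm,
  models cargo jittering by tens of nanometres — visually stationary at
  267 nm pixels.
- **Sub-diffusive**: fractional-Gaussian-noise increments with Hurst
  index `alpha_sub / 2`, scaled so the ensemble MSD is
  `4 D_free t^alpha_sub`. The fGn construction was chosen over obstacle
  or trapping models because its exponent is exact and analytically
  checkable; `alpha_sub = 1` degenerates to free Brownian diffusion,
  which is how Brownian study ensembles are produced. Increments are
  drawn via a cached Cholesky factor of the fGn correlation matrix.
- **Directed**: constant speed `v_directed` along a heading that
  performs a random walk (`heading_jitter`, default 0.1 rad/frame), plus
  an isotropic diffusive overlay (`D_directed_overlay`, default
  0.002 µm²/s) modelling cargo wobble around the track. Defaults mimic
  microtubule transport below 1 µm/s.

Independent Gaussian localization noise (`loc_noise_sigma`, default
0.02 µm — the middle of the instrument range) is added to every
coordinate at the end. All randomness flows from one explicit integer
seed per call through `withr::with_seed()`; the session RNG is never
touched, and identical parameters and seed reproduce output
bit-for-bit.

Whole-cell scenes add: a polygonal boundary (circular or smoothly
perturbed), trajectories seeded at 75–92% of the boundary radius, an
inward radial drift (`inward_drift_speed`) superposed on the motion
state, radial reflection at the boundary (cargo stays visible in-cell;
absorption would thin the ensemble unrealistically), two-state telegraph
blinking for single QDs, and pairwise fusion: each frame, any pair of
visible puncta closer than `fusion_radius` merges with probability
`fusion_rate`; the absorbed trajectory ends, the survivor carries the
summed base intensity, and aggregates stop blinking (as fused QDs do).
Fusion therefore conserves total base intensity exactly — the invariant
the intensity series relies on. Published quantitative blinking
statistics for QDs in this imaging regime are scarce, so the on/off
rates (0.3/0.1 per frame) are chosen for visual plausibility only and
are free parameters.

What the generator does *not* emulate: a realistic point-spread
function or camera noise model, 3-D motion, drift of the stage, linking
errors, or density-dependent detection failures. Tests passing on
synthetic data therefore validate the estimators' mathematics and their
behaviour under localization noise — not robustness to tracking
artifacts.

## Estimators

### Local MSD, anomalous exponent, diffusion constant

Around each point *i*, a centered window of `window_frames = 20` points
(truncated at the trajectory ends, `[i − w/2, i + w/2)`) supplies all
ordered pairs `(j, j + n)` for lags `n = 1…10`; their mean squared
planar displacement is the local MSD. A point is valid only if its
window has at least `n_max + 1 = 11` points, so the first point of a
trajectory (and nothing else, for tracks longer than 20 frames) is
flagged invalid rather than extrapolated.

The anomalous exponent α is the slope of the least-squares line through
(log lag, log MSD), zero entries excluded, at least three positive
points required. Log–log regression (rather than nonlinear least
squares) is deterministic and recovers exact power laws to machine
precision — the test suite asserts 1e-9.

The diffusion constant is `D = s/4` where *s* is the least-squares slope
of MSD versus lag over the first `d_fit_points = 5` lags **with a free
intercept**: static localization noise adds a constant `4σ²` to every
MSD value, and the free intercept absorbs it exactly. Negative slopes
clamp to `D = 0` with a flag.

### The noise floor and the exponent: a deliberate red flag

The same `4σ²` offset *cannot* be absorbed by a log–log fit. For free
diffusion the observed MSD is `4Dt + 4σ²`; at `D = 0.01` µm²/s, 10 Hz
and `σ = 20` nm, the offset is 40% of the lag-1 MSD and the deterministic
log–log slope over lags 1–10 is 0.88, not 1. A second, smaller effect
pushes the per-point estimate further down: a 20-frame window yields a
noisy MSD estimate, and `E[log MSD] < log E[MSD]` (Jensen), costing
another ≈0.06–0.09. The package's exponent-recovery study
(`study_exponent_recovery()`) reports ≈0.79 for noisy Brownian motion —
and the corresponding acceptance assertion of a `[0.9, 1.1]` recovery
band fails, intentionally left so. The bias is a property of the
published fitting procedure under realistic noise, not an implementation
defect: noise-free ballistic motion recovers α = 2.000 and the
fractional-noise generator at α = 0.75 recovers ≈0.68, both in band, and
exact power-law inputs are recovered to machine precision. Users
comparing exponents across conditions should remember that absolute α
values are compressed downward wherever the MSD approaches the noise
floor; *contrasts* between conditions measured at the same noise level
remain meaningful.

### Directional persistence

φ at point *i* is the mean cosine of turning angles between consecutive
raw displacement vectors inside the same 20-frame window; zero-length
steps contribute no angle, at least two usable angles are required.
φ = 1 for straight motion, −1 for a path reversing every frame, and the
ensemble mean is 0 for isotropic walks — that last property is what
pins the definition to *raw* steps: persistence computed on smoothed
(central-difference) velocities would be far more noise-robust, but
overlapping smoothed steps are serially correlated, which would make
even Brownian motion look persistent and break the zero-mean property.
The cost of the raw-step definition is real and quantified below.

### Directed state and segment extraction

A valid point is *directed* when `α ≥ 1.4` and `φ ≥ 0.7`. The printed
thresholds used historically for this kind of analysis are not
recoverable, so these defaults were set by two requirements — noise-free
ballistic motion always passes; Brownian motion passes in well under 1%
of points — and both are exposed in `analysis_config()`.

Maximal runs of consecutive directed points become segments when (a)
the run spans at least `min_directed_frames = 5` points, and (b) the
displacement across **every** rolling 0.5-s window inside the run
exceeds `min_displacement_um = 0.267` (one pixel). The rolling (rather
than whole-segment) reading is the stricter one and prevents a fast
run stitched to a stall from passing. One boundary case needs a
convention: a 5-point run spans only 0.4 s, so no full 0.5-s window
fits; the threshold is pro-rated by span (`0.267 × span/0.5`), which
preserves the per-time displacement requirement without exempting short
runs. Segment velocity is the mean of smoothed instantaneous speeds
`|r(i+h) − r(i−h)| / (2hΔt)` (`h = 2`) at the run's points.

The segment-recovery study embeds a 30-frame, 0.8 µm/s run in a
sub-diffusive background in 100 trajectories. Velocity recovery is
excellent (2–3% error) and no reported segment ever violates rule (a)
or (b) — but recall plateaus near 0.78 rather than the nominal 0.9: at
0.8 µm/s the per-frame step is 80 nm while the raw-step direction noise
is ≈35 nm per coordinate, so interior run points have φ = 0.75 ± 0.10
and ~27% of them dip below the 0.7 threshold, fragmenting the 5-frame
flag streak. This is the estimator's honest operating point at 20 nm
localization noise; raising recall requires either brighter/slower
imaging (lower σ), faster cargo, or a noise-robust persistence statistic
with the correlation caveat above.

### Mode classification and two-step statistics

A trajectory's mode comes from its mean valid local α with half-open
intervals: constrained `[0, 0.4)`, sub-diffusive `[0.4, 1.0)`,
super-diffusive `[1.0, ∞)` — boundary values deliberately fall upward,
and trajectories with no valid points are "unclassified" and excluded
from the three-way denominator. Population summaries are two-step: mean
within each cell first, then an unweighted mean (± SE) across cells, so
a cell with many samples cannot dominate a condition. Velocities bin at
5 min with every directed point as one sample; mode proportions bin at
15 min with each trajectory assigned by its midpoint (trajectories may
straddle bin edges). The two-step estimate is asserted equal to the
brute-force "mean over cells of per-cell means" to 1e-12.

### Endocytic ratio

For each punctum at distance `a > 0` from the annotated cell center,
`b` is the distance from the center to the first crossing of the ray
through the punctum with the boundary polygon (analytic ray–segment
intersection; an independent bisection oracle over point-in-polygon
tests agrees to 1e-6 on random star polygons). The frame ratio is
`mean(b/a)` — the formulation stated as an equation in the source
material; the alternative `mean(b)/mean(a)` reading is available as
`ratio_method = "ratio_of_means"` since the two conflict in prose, and
both give exactly 1 when all puncta sit on the boundary. Points exactly
at the center are excluded (the ratio is undefined there; a
measure-zero event). The series is smoothed by a centered 20-frame
moving average, truncated at the ends to preserve length; empty frames
stay as gaps and never enter the smoother.

One caveat the validation surfaces: under a *gentle* inward drift the
per-frame increase of the estimated, smoothed R is of order 1e-4 while
ensemble fluctuations of the mean-of-ratios statistic are larger, so
strict frame-by-frame monotonicity of the estimate is a seed-dependent
event even though the underlying (noise-free) mean distance-to-center
decreases strictly. The monotonicity study therefore uses a
drift-dominated scene (0.05 µm/s drift, D = 0.005 µm²/s, 50
trajectories, 300 frames), and even there a realization occasionally
shows a handful of non-increasing steps; the acceptance study reports
the monotone step fraction (typically 0.94–1.00) alongside the strict
assertion.

### Intensity series and colocalization

The per-frame mean punctum intensity is normalized to the first frame
containing a punctum. Because fusion conserves total intensity, the
normalized series equals (initial count / current count) in a
blink-free scene — an arithmetic identity the tests assert exactly.

Manders' M1 is `Σ red[green > T] / Σ red` with a strictly-greater
threshold (pixels exactly at T are excluded). T is either a number —
used for bit-exact tests — or Otsu's threshold of the green channel
(`EBImage::otsu`), the default because the historical analysis tool did
not record its rule; treat the threshold as a required, reported
configuration item in real studies. M1 is scale-invariant in the red
channel and monotone non-increasing in T; both are asserted, along with
exact agreement against a brute-force double-loop oracle. M2 is
provided for symmetry but unused by the pipeline.

## Pipeline, determinism and problem sizes

`run_simulate()` → `run_analyze()` → `run_coloc()` tie the stages
together. Every CSV output carries the run's configuration hash and
seed on a comment line; the manifest records per-cell trajectory
counts, and rerunning any stage with the same configuration and seed
reproduces every output byte-for-byte (asserted end-to-end). Per-cell
seeds derive from the master seed by a fixed affine map modulo 2³¹ − 1.

The validation studies run at sizes chosen to give stable estimates on
a single CPU in a few minutes: 200 trajectories × 200 frames per
exponent/diffusion ensemble, 100 embedded-run trajectories, 6 cells ×
15 trajectories × 300 frames per condition in the contrast study, 100
trajectories in the mode mixture, and 50-trajectory scenes for the
ratio studies. Enlarging them shrinks the Monte-Carlo error but does
not move the deterministic biases documented above.

## Known limitations

- Absolute α is biased downward near the localization-noise floor
  (quantified above); only same-noise contrasts are safely
  interpretable.
- Directed-segment recall degrades when `v_directed · dt` approaches
  the localization noise; at 0.8 µm/s and σ = 20 nm it is ≈0.78.
- The endocytic ratio assumes a star-shaped cell with respect to the
  annotated center (every ray hits the boundary once before leaving);
  strongly folded outlines violate this.
- No drift correction, 3-D motion, or HMM/Bayesian state inference;
  mode labels are whole-trajectory summaries and blur brief state
  visits.
- Blinking kinetics are schematic; conclusions about blinking
  statistics should not be drawn from the generator.
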
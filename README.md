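# qdtrack

Quantitative single-cell analysis of quantum-dot (QD) labeled endocytic
trafficking from single-particle tracking data.

After a ligand–receptor complex (for example EGF bound to its receptor,
labeled with a quantum dot) is internalized, the resulting endocytic
vesicles travel through the cytoplasm by a mixture of near-immobile
confinement, sub-diffusion in the crowded cytosol, and bursts of directed
transport along cytoskeletal tracks. `qdtrack` takes tracked trajectories
of such cargo (plus optional cell-outline annotations and two-channel
marker images) and quantifies this behaviour per cell:

- **Local MSD profiling.** Around every trajectory point *i*, the local
  mean square displacement over a 20-frame window,
  MSD(nΔt) = ⟨[r(t + nΔt) − r(t)]²⟩, n = 1…10, is fitted by the power law
  MSD ∝ t^α. α ≈ 1 indicates free diffusion, α < 1 sub-diffusion, α > 1
  super-diffusion (α = 2 ideal transport). The diffusion constant *D*
  comes from a linear fit MSD = 4Dt + c of the first 5 lags (the free
  intercept absorbs the static localization-noise offset), and the
  directional persistence φ is the windowed mean cosine of turning angles
  between consecutive steps (1 = perfectly straight).
- **Directed segments.** Points with α ≥ 1.4 and φ ≥ 0.7 are in the
  *directed state*; runs of at least 5 consecutive directed points whose
  displacement exceeds one pixel (267 nm) per 0.5 s are extracted as
  directed segments with run lengths and smoothed instantaneous
  velocities, v(i) = [r(i+h) − r(i−h)] / (2hΔt).
- **Motion modes.** Each trajectory is classified from its mean local α:
  constrained (α < 0.4), sub-diffusive (0.4 ≤ α < 1.0), super-diffusive
  (α ≥ 1.0); population statistics use a two-step average — per cell
  first, then unweighted across cells, in 5-min (velocity) and 15-min
  (mode proportion) bins.
- **Endocytic ratio.** For each visible punctum at distance *a* from the
  cell center, *b* is the center-to-boundary distance along the same ray;
  R = ⟨b/a⟩ is 1 when cargo sits at the cell boundary and grows as it
  approaches the center, tracing internalization progress over time.
- **Intensity aggregation.** Mean per-punctum intensity, normalized to
  its initial value; vesicle fusion conserves total intensity while
  reducing punctum counts, so this series rises as QDs aggregate.
- **Colocalization.** Manders' M1 — the fraction of red (QD) intensity on
  pixels whose green (e.g. EEA1 or LAMP-1) intensity exceeds a threshold
  (fixed or Otsu) — with per-condition/timepoint group statistics.

Because raw tracking data of this kind are rarely shared, the package
includes a first-class synthetic-data generator
(`simulate_trajectory()`, `simulate_cell_scene()`,
`render_two_channel_image()`) that emulates the acquisition regime —
10 Hz sampling, 267 nm pixels, 10–30 nm localization noise, Markov
switching among confined / sub-diffusive (fractional Gaussian noise) /
directed motion, inward drift inside a cell boundary, two-state QD
blinking, and intensity-conserving pairwise fusion — with full ground
truth, so every analysis stage is validated against known answers.

## Worked example

Simulate a control condition (directed speed 1.0 µm/s) against a treated
one (0.7 µm/s), three cells each, and run the full analysis:

```r
library(qdtrack)

cfg <- run_config(
  analysis = analysis_config(),
  motion = list(control = motion_params(v_directed = 1.0),
                treated = motion_params(v_directed = 0.7)),
  scene  = list(control = scene_params(n_trajectories = 20, n_frames = 300),
                treated = scene_params(n_trajectories = 20, n_frames = 300)),
  n_cells = 3, seed = 7
)
run_simulate(cfg, "demo/sim")
res <- run_analyze(cfg, "demo/sim", "demo/out")

res$binned_velocity
#>   bin_start_s bin_end_s n_cells mean_velocity_um_s se_velocity_um_s
#> 1           0       300       6          0.8784776        0.0594112
```

The pooled directed-motion velocity (0.88 ± 0.06 µm/s across the six
cells) splits by condition into 1.01 µm/s (control) and 0.75 µm/s
(treated) — a ratio of 0.74, recovering the simulated 30% slowdown:

```r
vel  <- res$segment_points
bv   <- function(sel) binned_velocity_stats(vel[sel, ], cfg$analysis)$mean_velocity_um_s
bv(grepl("treated", vel$cell_id)) / bv(grepl("control", vel$cell_id))
#> [1] 0.7385774
```

Trajectory mode labels and the endocytic-ratio series:

```r
head(res$modes[, c("traj_id", "mean_alpha", "mode")], 3)
#>   traj_id mean_alpha         mode
#> 1    t001  0.4915399 subdiffusive
#> 2    t002  0.3741941  constrained
#> 3    t003  0.8959116 subdiffusive

head(res$ratio_series[, c("frame", "t_s", "n_points", "R_raw", "R_smooth")], 3)
#>   frame t_s n_points    R_raw R_smooth
#> 1     0 0.0       19 1.184980 1.183463
#> 2     1 0.1       19 1.185279 1.183409
#> 3     2 0.2       19 1.184958 1.183380
```

R starts near 1.2 (cargo seeded near the cell boundary) and rises as the
inward drift carries vesicles toward the center. Colocalization against a
synthetic marker image with a constructed 35% overlap:

```r
img <- render_two_channel_image(overlap_fraction = 0.35, seed = 11)
manders_m1(img$red, img$green, "otsu")
#> [1] 0.35
```

Mode labels here are dominated by the sub-diffusive class because the
Markov state switching blends states within each trajectory — whole-
trajectory mean α rarely exceeds 1 unless transport dominates.

## Input formats

- **Tracker text**: ImageJ Particle Tracker report dialect — per-particle
  blocks starting `Trajectory k` (optionally `%`-prefixed), then
  whitespace-separated rows `frame x y z [m0 m1 …]` in pixel units;
  `read_particle_tracker_text()` converts to µm (default 0.267 µm/px) and
  takes `m0` as the intensity. Comment (`%`, `#`) and header rows are
  skipped; malformed rows are reported with their line number.
- **Trajectory CSV**: columns `cell_id, traj_id, frame, x_um, y_um,
  intensity`; 0-based frames, µm, image convention (y down).
- **Geometry JSON**: `{"units": "um", "boundary": [[x, y], …], "center":
  [x, y]}`; the polygon must be simple and the center strictly inside.
- **Images**: 8/16-bit grayscale TIFF pairs for `coloc_timecourse()`.

Trajectories shorter than or equal to 50 frames are removed by
`filter_trajectories()` before any dynamics analysis.

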
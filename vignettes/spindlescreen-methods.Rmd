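---
title: "Quantifying GSPC mitosis from spindle-pole tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GSPC mitosis from spindle-pole tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spindlescreen` quantifies mitosis in *C. elegans* germline stem and
progenitor cells (GSPCs) imaged in situ. Its starting point is the pair of
spindle-pole trajectories obtained by tracking a fluorescently tagged
beta-tubulin signal: the pole-to-pole distance (spindle length) follows a
stereotypical time course across mitosis, and the transitions in that curve
are usable as clocks. This vignette explains the models and conventions the
package implements, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The spindle-length clock

In a GSPC the spindle length trace has five phases: a roughly constant pole
separation before nuclear envelope breakdown (NEBD); a rapid collapse as the
poles move onto the nuclear remnant; a noisy plateau at the metaphase
spindle length; a rapid, approximately linear elongation after the
metaphase–anaphase transition (anaphase onset); and a telophase peak
followed by relaxation as the poles disassemble. Three landmarks are scored
on this curve:

* `t_nebd` — NEBD, the onset of the collapse;
* `t_s` — the "start" of mitosis, the first time point after NEBD at which
  spindle length reaches a stable minimum. The start, rather than NEBD, is
  the origin of the duration measurement because it is much less ambiguous
  on length traces and the NEBD-to-start interval is nearly constant across
  conditions;
* `t_ao` — anaphase onset, after which length increases rapidly.

**Mitotic duration** is `t_ao - t_s` (minutes). Mitotic delays produced by
spindle-assembly-checkpoint activity appear as a prolonged plateau.

### Automatic landmark scoring

Historically these landmarks are scored by clicking on length-versus-time
plots. `score_landmarks_from_length()` replaces the manual step with a
deterministic procedure; this is the central engineering decision of the
package, so its choices are spelled out:

1. The series is smoothed with a centred moving median (window
   `smooth_window = 3` frames) — robust to single-frame tracking glitches.
2. A plateau level `B` is estimated. The raw minimum is an extreme-value
   statistic: on a long plateau it sits ~2 SD below the true level, and a
   single deep noise excursion can anchor it arbitrarily low. `B` therefore
   starts from the median of the three smallest smoothed lengths and is
   re-centred on the median of all frames within the band
   `length <= B * (1 + delta)` until it stabilises (`delta = 0.10`).
3. The plateau band half-width additionally adapts to the measured plateau
   noise: it is at least `delta`, and at least `noise_mult = 2` SDs of the
   raw-minus-smoothed residuals of in-band frames (scaled by 0.64, the SD
   shrinkage of a median-of-3). Without this, cells whose length
   fluctuations exceed ~10% of the spindle length lose their late plateau
   frames from the band and their durations are truncated.
4. `t_ao` is the last in-band frame followed by a net smoothed-length rise
   of at least `rise_frac = 0.25` times `B` within `rise_window = 2.5`
   minutes.
5. `t_s` is the first in-band frame at a stable minimum: frames on the tail
   of the collapse, still dropping by more than half the band width to the
   next frame, are skipped.
6. `t_nebd` is the last frame before `t_s` on a locally decreasing run with
   smoothed length above `B * (1 + delta_nebd)`, `delta_nebd = 0.30`. If no
   such frame exists (shallow collapse), the cell is flagged
   `nebd_not_found` rather than guessed.

Ambiguous cells always carry `quality_flags` (`plateau_gap` for more than
`max_gap_frames = 2` consecutive missing plateau frames, mirroring the
tracker's gap allowance; `start_after_anaphase`; `nebd_not_found`), and
unscorable cells (no plateau, no elongation) error out per cell — in a
cohort run they are collected and reported, matching the practice of
discarding or manually rescoring ambiguous plots.

All thresholds are relative to `B`, so scoring is invariant to the length
unit, and only time differences matter, so it is invariant to time offsets.
On simulated tracks with durations of 2–25 min and 0.3 µm plateau noise the
median absolute duration error is at most one 0.5-min frame, the mean
signed bias is below half a frame, and roughly 2–5% of cells are rejected
as unscorable. Cells whose fluctuations are large relative to the plateau
(≳ 12% of spindle length) are still biased short by about a frame — see
Limitations.

### Chromatin-variance timing

When no spindle marker is available, mitotic timing is inferred from the
pixel-intensity variance of a histone-marker signal inside a 4.5 µm
circular nuclear ROI (`chromatin_variance_trace()`): variance is low in
interphase, rises sharply as chromosomes condense and congress after NEBD,
plateaus, and falls sharply as chromatin segregates out of the ROI at
anaphase. Per frame the ROI is measured on a mean projection of 5 z-slices
centred on the tracked nucleus, and the trace is min–max normalized.
`score_landmarks_from_variance()` scores NEBD as the last frame strictly
before the global maximum with normalized variance below 0.5, and anaphase
onset as the last frame above 0.7 (strict inequalities). Restricting the
NEBD search to frames before the maximum resolves the ambiguity that
"last frame below 50%" would otherwise also match post-anaphase frames.
Note this method measures NEBD-to-anaphase time, not start-to-anaphase
time, so its durations are systematically longer than spindle-derived ones
by the NEBD-to-start interval.

## The nine spindle features

`extract_features()` computes, per cell (windows closed at landmark frames;
"within 3 min prior" means the half-open window `(t_nebd - 3, t_nebd]`):

| Feature | Definition | Units |
|---|---|---|
| A | mean of the 3 largest lengths within 3 min before NEBD | µm |
| B | `t_ao - t_s` | min |
| C | mean length on `[t_s, t_ao]` | µm |
| D | SD of 7 randomly sampled length/C values from `[t_s, t_ao]` | — |
| E | mean frame-to-frame &#124;ΔL&#124;, % of C per minute | %/min |
| F | mean frame-to-frame axis angle / frame interval | °/min |
| G | least-squares slope of length vs time on `[t_ao, t_ao + 2.5]` | µm/min |
| H | F's formula on `[t_ao, t_ao + 2.5]` | °/min |
| I | second-largest length at `t >= t_ao + 7`, % of C | % |

Conventions the source definitions leave open, decided here and
configurable:

* **D** samples *without* replacement with an explicit per-cell seed
  recorded in the output, so this deliberately stochastic feature is
  reproducible. With fewer than 8 in-mitosis frames all frames are used and
  the cell is flagged.
* **E** uses the absolute frame-to-frame change: the feature measures
  fluctuation, and a signed mean would cancel to ~0 on any plateau.
* The spindle axis is undirected (pole labels are arbitrary), so F and H
  fold angles to at most 90°; an axis flip between frames contributes 0°.
* Ties for I's "second largest": rank 2 after a descending sort, duplicates
  permitted.
* A missing window (e.g. a movie that starts after NEBD) leaves that
  feature `NA` with a flag; the others are still computed.

## Cohort statistics

The screen-level statistics operate on a cells × features table with group
(genotype) labels:

* **Outlier removal** (`remove_outliers_per_group()`): per feature and per
  genotype, values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are set missing
  (the cell is kept for other features). The duration feature is never
  filtered — delays are the phenotype, not artefacts. Quartiles use linear
  interpolation between order statistics (`quantile` type 7); the rule is
  applied in a single pass.
* **Standardization** (`standardize_features()`): `(x - mu) / sigma` with
  the reference being the control group (for heatmaps, read literally as
  "number of control SDs from the control mean") or all cells pooled (for
  correlations and PCA).
* **Group tests** (`compare_groups_to_control()`): a Kruskal–Wallis omnibus
  test per feature, then Tukey–Kramer contrasts on mean ranks — the
  studentized-range distribution applied to rank differences with the
  tie-corrected rank variance and unequal group sizes. Only
  control-versus-group contrasts are reported, significant at adjusted
  p < 0.05. Exact p-values differ slightly from other implementations of
  the same post hoc; correctness is established by simulation properties
  (exchangeable groups are not significant, separated groups are, and the
  omnibus p tracks a permutation null at small n).
* **Duration correlations** (`correlate_features_with_duration()`): Pearson
  r of each feature (pooled cells) against duration, Bonferroni-corrected
  with m = 8 (all features except duration); non-significant correlations
  are reported as 0.
* **PCA** (`run_pca()`): eigendecomposition of the covariance of the
  standardized features via `prcomp`, complete cases only (listwise
  deletion after outlier removal — the default order, configurable), sign
  fixed so each loading's largest-magnitude element is positive. Run after
  outlier removal by default.
* **Delayed cells** (`classify_delayed()`): duration greater than the 90th
  percentile (type-7 interpolation) of the in-run control durations. On a
  large continuous control sample this labels 10% of control cells by
  construction.
* The pipeline aggregates per-gonad means alongside per-cell values; tests
  run at the per-cell level by default (`unit = "gonad"` switches to gonad
  means).

## Image quantifications

* **N:C ratio** (`measure_nc_ratio()`): mean fluorescence in a 4.5 µm
  nuclear disk over the mean in the surrounding annulus (radius enlarged by
  1 µm, nucleus excluded), both background-subtracted. Background is a
  constant, pooled pixels of rectangular ROIs outside the animal, or a
  matched autofluorescence image subtracted first. Neighbouring nuclei are
  excluded from the annulus via a mask; a fully covered annulus errors, a
  non-positive cytoplasm-minus-background is flagged undefined. The ratio
  is invariant to adding a constant everywhere and to gain. Pixel
  convention: 0-based indices, pixel centres at `(i + 0.5) * pixel_size`,
  rectangles half-open.
* **Pre-mitotic N:C** (`premitotic_nc()`): mean of the top 3 ratios at
  least 10 min before NEBD (after which nuclear accumulation begins to
  change); fewer than three eligible frames flags the value.
* **PZ nucleus counting** (`count_pz_nuclei()`): background subtraction
  (volume-median constant by default; a rolling alternative can be supplied
  as a constant), 3D median filter (x/y radii 2 µm, z radius 1 µm),
  Gaussian blur (sigma 2 *pixels* — interpreted in pixels, the convention
  of the GUI tools, and configurable), Difference-of-Gaussians at the
  estimated blob diameter (4.25 µm default), 26-neighbourhood local maxima
  above a threshold relative to the strongest response (hence invariance to
  intensity rescaling), greedy nearest-neighbour linking within 3.0 µm with
  up to 2 missed frames, and a count of tracks detected in at least 5
  frames. Greedy linking replaces a full assignment-problem linker: at PZ
  densities and 3 µm gates the two are equivalent, and the simpler linker
  is validated directly against generator ground truth. The 3D median,
  separable Gaussian and local-maxima kernels are small Rcpp routines.
* **Mitotic index** (`mitotic_index()`): mitotic cells over PZ nuclei.
  Mitotic cells (two discernible poles) are an input — in practice they
  come from pole-track pairing or manual scoring — not re-detected from
  pixels.
* **Assay ratios** (`assay_ratios()`, `error_class_test()`): class
  percentages for the three mitotic-error categories (none / metaphase
  misalignment / anaphase lagging-bridging), embryonic lethality as
  unhatched over total eggs, and a Fisher exact test on the collapsed 2×2
  error/no-error table.

## What the synthetic data emulate — and what they do not

Every stage is validated against generators with known ground truth:

* `simulate_spindle_track()` draws the piecewise kinematic profile
  (pre-NEBD separation → linear collapse → noisy plateau → linear
  elongation → telophase peak with relaxation at half the elongation rate,
  floored at 70% of the peak so the "second largest" telophase length is
  well defined), an angular random walk of the spindle axis, and a shared
  random-walk centroid drift. Gaussian noise is applied to plateau lengths
  only; landmark times snap to the frame grid.
* `simulate_chromatin_trace()` produces baseline → smoothstep rise over ~2
  frames → plateau → sharp exponential fall, attaining exactly its
  `baseline` and `peak` when noise-free, so the 50%/70% scoring rules
  recover the generating landmarks exactly.
* `render_nucleus_image()` draws an analytic disk/annulus geometry with
  optional neighbours, background and noise, with ground-truth masks.
* `simulate_pz_stack()` places nuclei at random positions at least one
  nucleus diameter apart (4.25 µm), renders the bright chromatin core as a
  Gaussian of FWHM 0.6 × nucleus diameter — a filled nucleus has much
  sharper edges than a Gaussian of its full size, and rendering at the full
  diameter would make realistically packed fields unresolvable for any
  detector — at 0.25 µm pixels and 1 µm z-steps over 8 frames with small
  per-frame jitter, plus Gaussian noise at the stated SNR (Poisson noise
  was judged unnecessary to exercise the detector's robustness).

The screen-scale cohort (`screen_group_specs()`) emulates the study
conditions: ten genotype groups of 35 cells over 7 gonad arms at 0.5
min/frame; a control with lognormal durations around 4.5 min (under 6 min
on average); three delayed groups with distinct spindle phenotypes
(+3.5 min with reduced plateau fluctuations; +2 min otherwise unremarkable;
+2.5 min with increased fluctuations and rotation); six groups drawn from
the control distribution. Spindle geometry: ~4 µm metaphase length, ~5.5 µm
pre-NEBD separation, 1 µm/min elongation, telophase peak at twice the
metaphase length, 0.3 µm plateau noise and 5°/min rotation for unperturbed
cells — illustrative magnitudes, not calibrated to real GSPC measurements,
which the original acquisitions do not print.

What the generator does **not** emulate: optical point-spread functions and
anisotropic blur, photobleaching, animal movement (registration is assumed
upstream), autofluorescent gut granules and other non-nuclear objects,
non-Gaussian intensity statistics, and correlated biological heterogeneity
between features beyond what the shared generative parameters induce.
Passing tests therefore demonstrate algorithmic correctness and stated
statistical guarantees, not segmentation performance on real micrographs.
In particular, the fraction of total variance on PC1+PC2 of the synthetic
feature table (37–42% across seeds) reflects the generator's correlation
structure, not the real screen's.

## Numerical choices and degenerate inputs

Percentiles and quartiles are `quantile` type 7 throughout. Ties at the
variance thresholds use strict inequalities (< 0.5, > 0.7). A flat variance
trace is a normalization error; an all-tied feature is flagged degenerate;
a zero-SD reference feature is dropped from standardization with a log; a
constant feature's correlation is reported as 0 and flagged. Linking breaks
distance ties by taking pairs in increasing-distance order. PCA requires
more complete cells than features. The D subsample, cohort seeds and
per-cell seeds all derive from a single master seed; generators restore the
caller's RNG state.

## Known limitations

* Durations of cells whose plateau fluctuations approach or exceed the
  adaptive band (≳ 12% of spindle length) are underestimated by about one
  frame on average, and moderate (~2 min) delays in such groups can fall
  below significance at screen-scale n with the conservative
  studentized-range correction across ten groups.
* A small fraction of simulated cells (2–5%) is rejected as unscorable at
  realistic noise; they are reported, not imputed.
* The variance-based duration is NEBD-to-anaphase, not start-to-anaphase.
* Tukey–Kramer-on-ranks p-values are asymptotic; at very small n (≤ 5 per
  group) they deviate from an exact permutation null by up to a few
  percent.
* The problem sizes used by the test-suite and the acceptance script (200
  tracks for recovery, 1000 null cohorts for error-rate control, one
  120-nucleus field, 10⁴ control durations) were chosen to make Monte-Carlo
  error small relative to each assertion's tolerance.
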
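---
title: "Measurement model and methods behind cmstrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement model and methods behind cmstrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model implemented by `cmstrack`, the
rationale for every default parameter, and the known limitations of both the
analysis pipeline and the synthetic-data generators.

# The test and its measurement model

The cervical movement sense test asks a person to trace a printed zigzag line
with a head-mounted laser pointer, using neck motion only. The target is a
1 mm-wide line of total length 1000 mm, folded into a zigzag on an A3 board
(420 × 297 mm). A camera films the board; the analysis proceeds in four
stages.

## 1. Target geometry and rectification

`buildZigzagPattern()` constructs the centerline as `2 * nPeaks` equal-length
segments between 11 vertices. The geometry is over-determined: given the
horizontal span (board width minus margins) and the total path length, the
peak amplitude follows as `A = sqrt(s^2 - dx^2) / 2` per segment; conversely a
requested amplitude fixes the span. Infeasible combinations (e.g. a 1000 mm
path that cannot fold into the requested board) raise
`geometryInfeasibleError`. A vertical pattern is the horizontal one rotated by
−90°, preserving the start corner's role.

Pixel-to-millimetre rectification is a planar homography estimated from the
four board corners by the direct linear transform (an 8 × 8 exact solve for
four correspondences). For exactly four corners the fit is exact up to
numerical precision; interior-point error under a synthetic projective camera
is below 0.5 mm when the corner coordinates themselves are exact. With
thresholded corner *detection* the interior error scales with the pixel
footprint of a millimetre (about 1.2 px/mm at 640 × 360), which the test suite
bounds separately.

Pixel convention: the centre of the pixel at row `r`, column `c` (1-based) is
at `(x, y) = (c - 0.5, r - 0.5)`.

## 2. Laser tracking

- **Board corners** (`detectBoardCorners`): luminance threshold 0.5 isolates
  the white board; the largest connected component's extremes of `x + y` and
  `x − y` give TL/BR and TR/BL. Accuracy on rendered frames is better than
  2 px.
- **Laser dot** (`detectLaserDot`): redness `R − (G + B)/2 > 0.2` with
  `R > 0.5`, connected components of area 3–500 px², keeping the blob with the
  largest summed redness-weighted intensity; the centroid is score-weighted
  (sub-pixel, < 0.5 px on rendered frames). Saturated white glare fails the
  redness test, which is the point of using redness rather than raw red.
- **Trajectory** (`buildTrajectory`): one sample per frame at the camera frame
  rate; dot radius in mm is derived from the local homography scale.
  `fillGaps()` linearly interpolates internal gaps of at most `maxGapFrames`
  (default 5, i.e. 0.2 s at 25 fps); longer gaps stay missing and count
  toward the QC missing fraction.

## 3. Trial segmentation and metrics

`segmentTrial()` finds the scored window:

- **Start**: the participant must dwell within `startRadiusMm` (15 mm) of the
  start vertex for at least `dwellS` (0.5 s); the trial starts when speed
  first exceeds `velocityOnsetMmS` (10 mm/s) after that dwell.
- **End**: the first frame that is *both* inside 15 mm of the end vertex *and*
  below the onset speed ("arrival-and-stop"). A pure first-entry rule would
  truncate the trial on any early fly-through of the end region; requiring
  the stop matches the protocol instruction to finish on the end point and,
  on scripted trials with a terminal hold, recovers the scripted duration
  exactly. If the dot never stops inside the end region, the frame of closest
  approach is used as a fallback.

Metrics over the window:

- **Time** = window length in seconds.
- **Acuity** = 100 × the fraction of non-missing samples whose
  point-to-centerline distance is within tolerance.
- **Speed** = traversed path length / time. Note this is the path *the dot
  travelled*, so tracking noise and overshoot inflate it above the nominal
  advance rate — a property of the measure itself, not an artefact.
- **NormAcuity** = Acuity / Time, the headline accuracy-speed-trade-off-free
  outcome.

**Tolerance policy**: the default on-line tolerance is
`lineWidth / 2 + median detected dot radius` in mm — a sample counts as on
the line when the dot's disc overlaps the printed line. When no radius is
available (e.g. synthetic tracks that never passed through a camera), a
2.5 mm radius is assumed, giving a 3 mm default tolerance.

Pooling (`poolTrials`) averages QC-passing trials; a direction with no usable
trial is an explicit `poolingError` rather than a silent mean over fewer
directions. QC fails a trial when its missing fraction exceeds `maxMissing`
(10 %).

## 4. Psychometrics

- **Normality gating**: Shapiro–Wilk at `alpha = 0.05`; non-normal variables
  are Ln-transformed and re-tested (`transformInfeasibleError` if any value is
  non-positive). Group comparisons and ICCs run on the gated scale;
  descriptives, SEM and MDC stay on the raw scale so they remain in clinical
  units.
- **Group comparison**: one-way ANOVA across CON / INP / TNP with pooled-
  variance pairwise t-tests and Bonferroni adjustment
  (`p_adj = min(1, 3 p_raw)`). Effect size is eta-squared (variance
  explained), not Cohen's d: with three groups a single d is undefined, and
  eta-squared is the quantity the ANOVA decomposition yields directly.
- **ROC**: AUC by the mid-rank Mann–Whitney statistic (ties counted ½), with
  a tie-corrected normal-approximation p-value. Direction `"low"` encodes
  that patients score *lower* on NormAcuity; the clinical cutoff (default
  2.5) classifies a score below the cutoff as a case, from which sensitivity
  and 1 − specificity are read off. The AUC matches `pROC` exactly; the
  p-value uses the normal approximation even at small n, where R's
  `wilcox.test` would switch to the exact distribution.
- **Reliability**: ICC(2,k) — two-way random effects, absolute agreement,
  average of k measurements — from the mean squares, with McGraw–Wong F-based
  confidence bounds stepped up by Spearman–Brown. Duplicated occasions
  (MSE = 0) are reported as exactly 1. SEM = SD(test2 − test1)/√2, so the SEM
  *is* the within-subject SD, and MDC = SEM × 1.96 × √2. Reported reliability
  arithmetic reproduces at one decimal: SEMs of 17.3 mm/s, 4.4 s and 0.4 give
  MDCs of 48.0, 12.2 and 1.1. (The corresponding published Acuity pair,
  4.5 → 12.6, is not arithmetically consistent — 4.5 × 2.7719 = 12.47 — and
  is therefore not asserted.)

# Synthetic data: what it emulates and what it does not

`trajectoryScript()` + `simulateTrajectory()` produce a constant- or
ramped-speed traverse of the centerline with optional Gaussian lateral error
(optionally AR(1)-correlated), a start dwell and an end hold, with exact
ground truth for time, speed and expected acuity. `renderFrames()` projects
board, line and dot through a pinhole camera (position, pitch/yaw/roll, auto
focal length from a fit fraction) into RGB frames, so the *entire* video
pipeline — corner detection, dot detection, rectification, segmentation,
scoring — can be exercised without real footage.

`simulateCohort()` draws subject-level true scores per group
(normal, between-subject SD), adds within-subject occasion error and a
second-occasion shift, and generates NDI scores bivariate-normally correlated
with Acuity. The defaults encode the group means, SDs, SEMs and retest shifts
reported for the clinical study populations (52 controls, 26 idiopathic and
28 traumatic neck-pain patients). Two of the published control-group SDs
(Acuity 1.7 %, NormAcuity 0.1) are implausibly small relative to the patient
groups and the reported SEMs; the simulator uses plausible values (11.7, 0.9)
of the same order as the other groups, since no derived quantity depends on
reproducing a likely typographical SD.

The generators deliberately do **not** emulate: motion blur, rolling shutter,
lens distortion, autofocus/exposure changes, hand-held camera shake, board
lighting gradients, or biomechanically realistic head kinematics (the lateral
error process is Gaussian/AR(1), not a motor-control model). Glare is modelled
only as a static white Gaussian blob.

## Vertex bias in the closed-form acuity check

For lateral error `e ~ N(0, sigma)` about a *straight* line, expected acuity
is exactly `100 (2 Φ(τ/σ) − 1)` — 68.27 % at `τ = σ`. On a zigzag this closed
form is only a lower bound near vertices: the distance to the polyline is the
minimum over both adjacent segments, which shortens distances in the vertex
wedge and biases measured acuity slightly upward. The closed-form agreement
checks therefore run on a degenerate single-segment (straight) pattern; the
zigzag tests use Monte-Carlo tolerances instead.

# Problem sizes used in validation

The automated suites run at desk scale, chosen to keep the full test run
around a minute while leaving Monte-Carlo error well inside the asserted
tolerances: renders at 640 × 360 (unit tests) and 960 × 540 (end-to-end),
25 fps; 200 trials for the closed-form acuity comparison (99 % CI of the MC
mean); 500 simulated cohorts of n = 50 × 2 occasions for ICC/SEM recovery;
1000 random queries against a 0.01 mm brute-force distance oracle; exhaustive
pair-counting AUC oracles at n ≤ 12.

# Limitations

- No built-in video decoding: inputs are PNG frame directories or in-memory
  frame sources; decode video externally (e.g. `ffmpeg`).
- Corner detection assumes the board is the largest bright region and fully
  in view; heavy occlusion or a bright background defeats it.
- The rectification is planar: a bowed board violates the homography model.
- ROC p-values use the normal approximation (see above); at very small n
  prefer an exact method if the p-value itself is the object of interest.
- ICC confidence bounds use the Spearman–Brown step-up of the single-measure
  F bounds, which is the standard but slightly conservative construction.
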
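---
title: "Movement-quality assessment from pose-landmark trajectories"
author: "rehabDTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-quality assessment from pose-landmark trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabDTW)
```

## The problem and the model

Home rehabilitation exercises are usually performed without supervision.
If a smartphone video of the exercise can be reduced to a pose — the 3-D
positions of 33 anatomical landmarks per frame — then "how well was this
exercise performed?" becomes "how far is this landmark time series from a
clinician's reference performance?". That reframing drives every design
choice in this package.

A recording is a `LandmarkTrajectory`: a frames × 33 × 3 array of
coordinates plus per-landmark visibilities. Coordinates are expected in
*world space* — meters, origin at the hip midpoint — because world
coordinates are invariant to where the subject stands in the image.
Normalized image coordinates are accepted, but every comparison involving
them warns: two identical movements filmed from different distances would
otherwise look different. The package treats the axis conventions of the
upstream pose model as opaque: nothing depends on which way y points, and
no axis transformation is applied.

For each landmark, the time-ordered (x, y, z) triples form a sequence.
Two recordings are compared landmark by landmark with dynamic time
warping (DTW). The accumulated-cost grid is defined over the sequence
elements themselves: cell (1, 1) holds the point distance between the
first elements, first row and column accumulate along the grid edge, and

$$D(i,j) = \mathrm{Dist}(A_i, B_j) + \min\,[\,D(i-1,j),\ D(i,j-1),\ D(i-1,j-1)\,]$$

fills the rest. The distance is the value at $D(|A|,|B|)$; the warp path
is recovered by backtracking and always covers every index of both
sequences monotonically. With this indexing the canonical shifted pair
$A' = [0,1,2,3,0,0]$, $B' = [0,0,1,2,3,0]$ has DTW distance exactly 0,
while its index-aligned Euclidean distance is $\sqrt{12} \approx 3.46$ —
the property that motivates using DTW at all, and the package's reference
check.

Per-landmark distances are summed within clinically defined joint groups
(Head: landmarks 0–10; Trunk: 11, 12, 23, 24; Shoulder: 12, 14, 16) into
a per-trial distance table; distances become 0–100 quality scores by
per-group normalization with scale inversion; repetition scores average
into per-subject scores; and those are compared to gold-standard scores
with MAE, RMSE, Pearson correlation and a Wilcoxon signed-rank test.

## Parameters that matter

* **Point metric** (`metric`, default `"euclidean"`): the distance between
  two aligned (x, y, z) triples, in meters. Euclidean is the default
  because it performs best for movement comparison; Manhattan is provided
  for sensitivity analysis.
* **Multivariate handling** (`type` in `landmarkDtw()`, default
  `"dependent"`): the point metric acts on the whole coordinate triple at
  each aligned pair, because the landmark sequence is a sequence of
  triples, not three unrelated scalar series. The `"independent"` variant
  (one scalar DTW per axis, summed) exists because pose-comparison
  pipelines are not always explicit about this choice; results using it
  should say so.
* **Warping window** (`window`, default unconstrained): a Sakoe–Chiba
  band half-width, available for diagnostics. The assessment pipeline
  never constrains the alignment, and no step weighting or path-length
  normalization is applied — accumulated distances therefore grow with
  recording length, which is why calibration is per batch and per group.
* **Normalization** (`normConfig()`): per joint group and per exercise
  batch; group distances are never pooled. For min–max, `min = 0`
  (a perfect performance has distance 0) and `max` defaults to the
  per-group batch maximum; an explicit calibration maximum — the distance
  between two deliberately very different recordings — is the better
  choice when scores must be comparable across batches. Because all
  distances are non-negative and min is 0, max-abs scaling is identical
  to min–max (the package tests this equivalence byte for byte).
  Scores are clipped to [0, 100] by default; `clip = FALSE` exposes
  negative scores for diagnostics. The chosen calibration is recorded in
  the output's `normalization` attribute because scores are meaningless
  without it.
* **Z-score mapping** (`center = 50`, `spread = 25`): standardized
  distances are placed on the score scale by `score = center − spread·z`.
  No principled 0–100 embedding of z-scores exists — any affine works and
  changes MAE/RMSE while leaving the Pearson correlation untouched (the
  package tests exactly this invariance). The defaults put the batch mean
  at 50 and ±2 standard deviations at the scale ends. Comparisons of
  error metrics under z-scoring are therefore calibration-relative;
  the correlation is the robust quantity. The standardization uses the
  population standard deviation of the batch.
* **Visibility** (`maskLowVisibility()`, default off): visibility is
  carried but never used for weighting or masking unless explicitly
  requested, since the assessment method itself makes no use of it.

## The evaluation layer

MAE and RMSE are reported on the 0–100 score scale; RMSE ≥ MAE always,
with the gap measuring the influence of large errors. The Pearson
correlation is undefined for constant series and reported as `NA` with a
warning rather than a number.

The Wilcoxon signed-rank test is implemented from first principles:
differences `predicted − actual`, zeros dropped (Pratt's variant — rank
first, then drop the zeros' ranks — is available via `zeroMethod`),
absolute differences ranked with average ranks on ties, and the statistic
`R = min(R₋, R₊)`. The two-sided p-value is exact up to 25 effective
pairs: the null distribution of R₊ is built by convolution over the
observed rank multiset (ranks doubled so half-ranks index an integer
grid), which handles ties exactly and is independent of the test suite's
brute-force 2ⁿ enumeration oracle. Beyond 25 pairs a normal approximation
with tie-corrected variance and a 0.5 continuity correction takes over;
the suite checks it stays within 0.01 of the exact value at n = 20.
Two-sided p-values are used throughout, and no multiple-comparison
correction is applied by default (matching common practice in small pilot
evaluations); both choices are deliberate and documented rather than
configurable hidden state. When every non-zero difference shares one
sign, `R` is necessarily 0; the result is flagged `degenerate` and the p
comes from the actual null distribution rather than being reported as a
hard zero, because a boundary statistic carries little information about
systematic offset.

Outliers are removed at the (subject, joint group) level only: clinical
outlier flags in this setting name a single measurement, and removing the
whole subject would discard valid data in the other groups. The removal
log is part of the evaluation report.

## What the synthetic generator emulates — and what it does not

`generateCohort()` reproduces the *design* of the study this pipeline
targets: 15 subjects × 3 repetitions of one exercise plus one reference
recording, world coordinates at 30 frames/s. Motion is modelled as
per-landmark sinusoidal displacement around a plausible resting pose —
the simplest deterministic signal with controllable amplitude, frequency
and phase. Trials deviate from the reference through four orthogonal
knobs: amplitude scaling (the graded "performance quality" axis, default
grading 0–0.6 across subjects), leading idle time, a smooth monotone time
warp, and additive Gaussian coordinate noise; a single master seed
derives all per-trial seeds, making cohorts bit-reproducible. Synthetic
gold scores are `100·exp(−deviation/τ)` with τ = 0.25 — any strictly
decreasing map suffices for recovery testing, and an exponential keeps
gold scores in a realistic 9–100 range over the default grading; the map
is recorded in `ground_truth.csv`.

What passing tests on this cohort demonstrate: the pipeline's ordering
behaviour (larger injected deviation ⇒ larger distance ⇒ lower score,
rank correlation ≤ −0.9 at zero noise), its shift invariance (pure idle
prefixes score ≈ 100), and the end-to-end plumbing. What they do *not*
demonstrate: robustness to real pose-estimator error structure (depth
noise is not isotropic Gaussian; occlusion produces correlated dropouts,
not independent jitter), to biomechanically realistic kinematics, or to
inter-subject anthropometric variation. Results on synthetic cohorts
bound what the arithmetic does, not what a clinical deployment would see.

## Numerical choices and degenerate inputs

* DP indexing starts at the first element pair — there is no virtual zero
  cell — which is what makes the worked shifted-pair distance exactly 0.
* Backtracking tie-break: diagonal, then vertical, then horizontal, on
  equal predecessor costs. Paths are therefore deterministic; the
  distance never depends on the tie rule.
* Sequences of length 1 are valid for DTW (the path degenerates to edge
  moves); empty sequences are errors. Trajectory comparisons require at
  least 2 frames.
* CSV trajectory output carries 6 decimal places (≈ micrometer precision
  in world space, far below pose-estimator noise); JSON carries full
  precision. Read–write round-trips are tested at those tolerances.
* Min–max with `max ≤ min`, z-scoring a zero-spread group, ROM of an
  empty series, a zero-length joint-angle arm, and an all-zero-difference
  signed-rank test all fail loudly with the offending group or input
  named — none return silent sentinel values.
* Backend frames that fail pose estimation are dropped (and counted in
  the trajectory metadata) rather than imputed: DTW tolerates unequal
  lengths, and no imputation rule would be better than none.

## Problem sizes

The shipped tests and examples use cohorts of 15 × 3 recordings of 120
frames (4 s at 30 fps) for end-to-end checks — the full study geometry —
and shorter sequences (≤ 6 points) where exhaustive warp-path enumeration
serves as the oracle; the brute-force oracle is exponential and is a test
instrument, never a runtime path. The Rcpp dynamic program is O(|A|·|B|)
per landmark; a full 45-trial batch over the three default joint groups
(18 distinct landmarks) completes in about a second on one core.

## Known limitations

* Pose estimation itself is outside the package: `estimateTrajectory()`
  defines an adapter contract (frame → 33 × 4 matrix) and a reader
  injection point, but ships no video decoding or network inference.
* Scores are calibration-relative. A min–max score of 60 means nothing
  without the batch (or explicit maximum) that produced it; the package
  records calibrations in outputs but cannot make scores portable.
* Accumulated DTW distance grows with recording length; comparing scores
  across recordings of very different durations requires an explicit
  calibration, not the batch default.
* The ROM quality index uses a generic vertex-angle range; full clinical
  key-point protocols for specific joints are out of scope.
* Uniform landmark weighting within groups; no velocity/acceleration
  features; no real-time feedback loop.
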
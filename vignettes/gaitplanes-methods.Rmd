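---
title: "Body-axis planes, tolerance ellipses and gait parameters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body-axis planes, tolerance ellipses and gait parameters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitplanes)
```

## The measurement and its coordinate problem

The input to `gaitplanes` is what a monocular markerless motion-capture app
exports while a subject walks around a 1 m diameter circle twice: for each
of 24 named keypoints, per-frame 3D coordinates at 30 fps, *relative to the
body center* and normalized to body scale, plus a per-keypoint confidence
score in [0, 1]. Entries with confidence below 0.7 are treated as
unreliable pose estimates and masked (never deleted — frame alignment
across keypoints is preserved, and downstream fits count usable points
exactly).

Circular walking means the subject's orientation sweeps ~720° per
measurement, so keypoint clouds in camera coordinates are smeared into
rings. The pipeline therefore rebuilds a body-centric orthonormal frame
*every frame* from the trunk itself and projects all keypoints into it.
Recomputing per frame (rather than once per measurement) is essential for
this protocol; a fixed frame would reintroduce the orientation sweep.

## Body axes

Per frame, with all of navel, shoulders and hips unmasked:

* `UF` = unit normal of the plane (navel, r shoulder, l shoulder);
  `DF` = unit normal of the plane (navel, r hip, l hip). The two trunk
  triangles face opposite directions (the navel lies below the shoulders
  but above the hips), so the cross-product edge order differs per plane to
  bring both normals to the same side of the trunk.
* `f = normalize(UF + DF)`. Equal weighting is the symmetric reading of a
  "composite" of two unit normals; no anatomical argument favors either
  plane.
* `c` (lower limb) is the unit vector toward the hip midpoint, `cc` (upper
  limb) toward the shoulder midpoint, each orthogonalized against `f`;
  `n = f x c` (or `f x cc`). Orthonormality holds to 1e-9 by construction
  and is asserted per frame in the tests.

Two *measurement-level* sign conventions remain, because the handedness of
an app's coordinate export cannot be recovered from anatomy alone:

* **Forward sign.** Default anchor: the mean of (toe midpoint − heel
  midpoint) must have a non-negative component along `f` — feet point
  forward during gait. We deliberately do not anchor on navel velocity: in
  body-center-relative coordinates the navel sits essentially at the
  origin, so its velocity is numerically degenerate on exactly the data
  this pipeline consumes. A `"velocity"` option (5-frame window) is kept in
  `gait_config()` for inputs that retain global translation.
* **Lateral sign.** `n` is flipped, if needed, so the right hip (right
  shoulder for the upper segment) has positive mean lateral coordinate:
  axial x > 0 is the subject's right. Outward-shift signs depend on this.

Projections: for `d = p − navel`, sagittal = `(d·f, d·c)`, coronal =
`(d·f, d·n)`, axial = `(d·n, d·c)` (with `cc` for upper-limb keypoints).
Lower-limb coordinates are divided by the total leg length, defined as the
per-side median over frames of `|hip→knee| + |knee→heel|`, averaged over
sides; upper-limb coordinates by the median `|navel→head|`. The toe segment
is excluded from the default leg length (the toe keypoint is the noisiest
and the definition with heel endpoint is the conservative one);
`gait_config(leg_definition = "hip_knee_heel_toe")` switches conventions.
After normalization the planar series are invariant to global translation,
rotation and scale — verified as property tests at 1e-6.

Frames with masked trunk anchors are skipped, not interpolated:
interpolation would manufacture data precisely where the pose estimator
failed.

## Tolerance ellipses

For each keypoint and plane the 2D cloud is summarized by a coverage
ellipse under a bivariate normal model: center = sample mean, axes from the
eigen-decomposition of the sample covariance (n−1 denominator), semi-axes
scaled by `sqrt(qchisq(coverage, 2))` with coverage 0.75 by default. This
is the "75% tolerance ellipse" of the posturography tradition — a
population-coverage ellipse, not a tolerance *region* with a confidence
level on the coverage; the latter reading would need an extra confidence
parameter nothing in the protocol supplies. The empirical check: on 10^5
standard-normal draws the fitted ellipse contains 75% ± 1% of the sample.

Numerical choices:

* **Area** = π · semi-major · semi-minor, the true geometric area (a circle
  of radius r has area πr²). The phrase "major axis × minor axis × π" is
  ambiguous between semi- and full-axis lengths (full axes give 4× the
  geometric area); `gait_config(axis_convention = "full")` reproduces the
  other reading for compatibility experiments.
* **Tilt** is reported in (−90°, 90°]; isotropic covariances (eigenvalue
  gap below 1e-9 relative) report tilt 0 deterministically.
* **Degenerate clouds** are not errors: identical points give both
  semi-axes 0; collinear clouds give semi-minor 0, so angle ranges stay
  computable. The membership test is the one operation that requires a
  non-degenerate ellipse.
* **min_points = 10** complete points per fit; cells below that are
  flagged missing, and missingness propagates to cohort statistics as
  deficit data rather than zeros.

## Gait parameters

* **Joint angle range**: the angle at the proximal joint's ellipse *center*
  subtended by the two endpoints of the distal joint's ellipse major axis;
  pairing shoulder→elbow, elbow→hand, hip→knee, knee→heel. Note the
  endpoints of a tolerance ellipse extend beyond the raw data extremes, so
  a ±A° joint oscillation yields a range larger than 2A — the parameter is
  an ellipse-based surrogate for joint excursion, not a goniometric range.
  A fully degenerate distal ellipse gives 0°.
* **Outward shifts** (axial plane): right-side deviation = distal center x
  − proximal center x; left-side = its negation; positive = outward.
  leg = heel + toe and arm = elbow + hand hold *exactly*, always. The
  bilateral value is the mean of the two sides (not the sum), keeping the
  unit interpretable as a fraction of leg (or upper-body) length;
  `gait_config(bilateral = "sum")` switches.
* Reported values are left/right and their mean; correlation analyses use
  the left–right means on the sagittal plane by default.

## The synthetic walker

`generate_walk()` emulates the measurement protocol so every stage is
testable without recordings: a rigid-segment walker (trunk, two-segment
arms and legs) circles a 1 m diameter path twice with heading tangent to
the path, sinusoidal joint oscillations, contralateral limbs in antiphase,
a small (2°) physiological trunk sway, additive i.i.d. Gaussian coordinate
noise (default SD 0.01 in export units), and a two-point confidence
mixture (0.95 normally, 0.5 with probability 0.05). Walk duration follows
from the cadence-derived speed (step length 2·L·sin(hip amplitude), two
steps per cycle), giving ~150 frames for the healthy preset and ~460 for
the slow HD preset.

Two constructions make noise-free ground truth *exact* rather than
approximate, which the recovery tests exploit at 1e-9:

* lateral offsets are folded into unit segment directions, so
  `|hip→knee| + |knee→heel|` equals the configured leg length in every
  frame, and heel/toe (elbow/hand) ellipse-center deviations equal the
  configured offsets exactly;
* the "smoothed" variant low-pass filters only the additive noise component
  (4th-order Butterworth, 6 Hz): the kinematic signal is band-limited well
  below the cutoff, and filtering it too would distort the exact-recovery
  contract between generator and pipeline.

Archetype presets encode disease-typical signatures as orderings, not as
patient-level means: hip/knee amplitudes healthy (25/30°) > CM (18/22°) >
PD (12/15°) > HD (7/9°); shoulder/elbow amplitudes healthy (18/12°) >
CM (13/9°) > HD (8/6°) > PD (4/3°); leg lateral offsets healthy (−0.03,
inward) < CM (0.03) < PD (0.09) < HD (0.18 — above 15% of leg length, the
wide-based regime); arm lateral offsets healthy > CM > HD > PD. The
amplitude values themselves are plausible round numbers chosen once to
realize these orderings with comfortable margins; they are not fitted to
any cohort. `generate_cohort()` adds per-subject log-normal jitter
(sdlog 0.15), a shared per-subject mobility factor on the hip and elbow
amplitudes (sdlog 0.25) that induces the upper–lower limb coupling the
correlation analysis is designed to detect, and per-measurement jitter
(sdlog 0.05). Demographics (sex ratios, truncated-normal ages per group)
emulate a typical neurology clinic cohort.

What the generator does **not** model — and hence what passing tests do
not show about real data: ground contact and balance dynamics, pose-
estimator biases (which are structured, not i.i.d. Gaussian), asymmetric or
fluctuating gaits, freezing episodes, and any intervention effects. The
generator validates the *measurement pipeline*, not clinical claims.

## Cohort statistics

Pearson's r with a Fisher-z 95% CI (`atanh(r) ± qnorm(0.975)/sqrt(n−3)`),
after pairwise deletion of missing values; |r| = 1 reports the degenerate
interval [r, r]; fewer than 3 complete pairs or zero variance are flagged,
not computed. Measurements (not subjects) are the correlation unit, so
repeated measures per subject are treated as independent — a deliberate
simplification that inflates effective n; a mixed-effects treatment is out
of scope and the caveat applies to any table produced here. Cells with
|r| > 0.3 are highlighted in the export. p-values are omitted by default
(r and CI carry the information).

## Problem sizes and runtime

Test and acceptance workloads are sized for a single CPU: coverage checks
at 10^5 draws (binomial error ±0.4%, tolerance ±1%), ordering checks at
20 walks per group and one lap-pair each, sweeps at 5 design points, and
the full cohort-arithmetic check (427 subjects, 1491 measurements) at
metadata level (`simulate = FALSE`), which is instant. These sizes are the
package's own choices; all scale linearly if a user wants tighter Monte
Carlo error.

## Known limitations

* The CSV dialect is a documented stand-in: the real app's column naming is
  not public, so `read_keypoint_csv()` documents and enforces this
  package's dialect (suffix pairs `_raw`/`_smooth`, masked cells empty).
* Coordinates are floor-free by design; stride length in meters, gait
  events and ground-referenced quantities are out of scope.
* Whether the app's confidence is per keypoint or per frame is not
  documented; the filter assumes per keypoint per frame, the stricter and
  more general reading.
* The 19 pipeline keypoints are fixed; the other 5 vocabulary slots are
  free named columns carried through I/O untouched.
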
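---
title: "Muscle-tendon morphometry and gait kinetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-tendon morphometry and gait kinetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmorph)
```

## What the package computes

`tsmorph` implements the measurement chain used to study how triceps
surae muscle size, Achilles tendon morphology, and ankle function
relate to each other in young and older adults:

1. **Muscle volumetry** from 3-D label maps: per-muscle volume for the
   posterior soleus (PS), anterior soleus (AS), medial gastrocnemius
   (MG), and lateral gastrocnemius (LG); volumes relative to the group
   total; and volumes normalized by body size (height × mass).
2. **Achilles free-tendon geometry**: per-slice cross-sectional area
   (CSA), centroid-path length, volume, and the mid-length CSA used as
   the representative tendon size.
3. **Moment arm**: the perpendicular distance between the tendon's line
   of action and the ankle's functional (screw) rotation axis,
   evaluated at the neutral (0°) posture via a quadratic fit over the
   swept angle range.
4. **Gait kinetics**: sagittal-plane inverse dynamics of treadmill
   walking, reduced to per-cycle peak plantarflexion torque,
   spatiotemporal parameters, and an estimated peak tendon force
   (torque / moment arm).
5. **Cohort statistics**: exact Mann-Whitney rank-sum comparisons with
   uncapped Holm step-down correction over per-muscle families, and
   linear scaling regressions within groups.

Because subject-level imaging and gait data of this kind are not
publicly distributable, every stage is paired with a synthetic-data
generator whose ground truth is known exactly, so the full chain is
verifiable end to end.

## Measurement models

### Volumetry

A label volume is an integer grid with voxel spacing $(d_x, d_y, d_z)$
in mm; volume of a label is (voxel count) × $d_x d_y d_z$, reported in
cm³. This voxel-counting model is mirrored in the phantom generator: a
voxel carries a label iff its **center** lies inside the analytic shape,
with no partial-volume weighting. Under this rule the rasterization
error of an ellipsoid at the acquisition spacing (0.72 × 0.72 × 2 mm)
is below 0.1% for muscle-sized shapes, and shrinks roughly in
proportion to the spacing (the boundary-shell volume is $O(h)$).

### Tendon geometry

The free tendon spans the slices between two landmark slices: the most
proximal slice where the calcaneus is visible (0% of normalized length)
and the soleus muscle-tendon junction (100%). These come from landmark
labels in synthetic volumes or from a JSON sidecar for externally
segmented data; both paths are identical downstream. Per-slice CSA is
measured **in the axial plane** (voxel count × in-plane voxel area),
deliberately not perpendicular to the local tendon direction — this
matches the slice-wise measurement convention of the imaging protocol
the package emulates, and the perpendicular correction is intentionally
not applied. Tendon length is the summed distance between centroids of
adjacent slices, so an inclined tendon is longer than its axial extent
by $1/\cos\theta$. The representative "mid-length" CSA is taken at the
slice whose cumulative centroid-path length first reaches 50% of the
total; for a straight tendon with an even slice count this picks the
lower of the two central slices. The 50%-of-path rule is robust to
curved tendons and deterministic.

### Functional axis and moment arm

Marker clusters (≥3 non-collinear markers) give least-squares rigid
poses via the SVD/Kabsch solution with reflections excluded. Foot
poses relative to the shank over a dorsiflexion-to-plantarflexion sweep
are reduced to finite helical axes, one per pose pair spanning at least
5° (smaller displacements give noise-dominated axes). All qualifying
pairs are used, not only consecutive ones: weighting the direction
average by rotation magnitude lets the wide-spanning, least
noise-sensitive pairs dominate, which is what brings the axis direction
error below 1° at 0.5 mm marker noise (about 95% of trials at a
30-40° sweep; consecutive minimal-span pairs alone leave errors of
several degrees). The axis point is the least-squares point closest to
all helical axes; its component along the axis direction is
unidentifiable for a hinge and is pinned to the weighted mean axial
position of the helical-axis points.

The ankle angle of a frame is the signed rotation of its pose about the
functional axis relative to the neutral calibration pose, with the axis
oriented so dorsiflexion is positive. This convention is self-consistent
with the axis being the only rotation model available; it is a design
choice, since segment-axis angle definitions would require additional
anatomical calibration.

The tendon line of action is the total-least-squares line (first
principal direction) through the superficial/deep edge-pair midpoints
after transformation into the shank frame. The moment arm is the
skew-line distance

$$d = \frac{|(\mathbf{p}_1 - \mathbf{p}_2) \cdot
(\mathbf{d}_1 \times \mathbf{d}_2)|}{\lVert \mathbf{d}_1 \times
\mathbf{d}_2 \rVert},$$

with a point-to-line fallback for (near-)parallel lines, which is the
exact limit. The neutral-posture moment arm is the constant term of an
ordinary least-squares quadratic of moment arm against angle, fitted
over the observed range only.

### Inverse dynamics

The sagittal plane (x anterior, y vertical) Newton-Euler balance on the
foot segment gives the net ankle moment from the ground reaction force
at the center of pressure, the foot's weight, and the inertial terms
$m\mathbf{a}$ at the COM and $I\alpha$. The sign convention is
plantarflexion positive: a vertical GRF applied anterior to the ankle
produces a positive moment (735.75 N at 0.12 m gives exactly 88.29 Nm
with a massless foot). A full 3-D model would add out-of-plane terms
the sagittal outcome does not need; the planar formulation is a
deliberate, fully testable simplification. Gait events come from a
20 N threshold on the (filtered) vertical GRF with a 50 ms debounce.
Force channels are low-pass filtered at 25 Hz and kinematics at 6 Hz
(2nd-order Butterworth run forward and backward: 4th-order zero-lag
response) — conventional gait defaults, declared rather than inherited
from any particular acquisition system. Foot anthropometrics default to
a mass fraction of 0.0145 of body mass, COM 7 cm anterior and 3 cm
inferior to the ankle, 5 cm radius of gyration; a missing foot model
falls back to these with a warning. Per-cycle waveforms are
time-normalized to 101 points from heel strike to ipsilateral heel
strike, and peaks are averaged across cycles. On a treadmill, stride
length is belt speed × stride time, step length half of it (symmetric
default), cadence 120/stride time.

### Statistics

The Mann-Whitney U is computed from midranks. With pooled $n \le 25$
and no ties the two-sided p is exact: the permutation distribution of U
is enumerated by the classic count recursion, and p = 2 × the smaller
tail probability, capped at 1. The 25-subject cutoff covers the 14 + 7
design with instant enumeration. With ties or larger samples a normal
approximation with tie correction and 0.5 continuity correction is
used. The doubling dialect (rather than summing both tails beyond the
observed statistic) is documented because packages differ.

Holm's step-down correction multiplies the i-th smallest p by
$(m - i + 1)$ and enforces monotonicity. Adjusted values are **not
capped at 1 by default**, so the full step-down products remain
visible (a capped variant is available via `cap = TRUE`). Families are
exactly the four per-muscle repetitions of a test; single-measure tests
(total volume, tendon CSA, torque) are unadjusted.

Simple regressions are computed from the closed-form normal equations
with the slope t-test on $n - 2$ degrees of freedom; the test suite
cross-checks every statistic against `lm()` and literal enumeration
oracles.

## The synthetic cohort: what it emulates

The generator's defaults encode the study conditions the package is
built around: 14 young and 7 older adults; height 1.78 ± 0.10 /
1.76 ± 0.07 m and mass 74.87 ± 12.11 / 74.57 ± 15.26 kg; total triceps
surae volume scaling at 7.00 (young) vs 5.95 (older) cm³ per kg·m of
height × mass; muscle fractions (PS, AS, MG, LG) ≈ (0.42, 0.09, 0.31,
0.18); moment arm 46.64 ± 3.87 / 43.54 ± 8.13 mm; and peak walking
torque scaling ≈ 0.86 / 0.81 Nm per kg·m. The structural contrast under
study is encoded **only** through generator parameters: in the young
group tendon CSA is a linear function of total muscle volume
(0.05 mm²/cm³ + 16.56 mm², residual SD 5.5 mm²), while in the older
group CSA is drawn independently of volume (65.54 ± 6.96 mm²). The
analysis modules contain no group-conditional logic, so any young/older
difference the pipeline reports is carried entirely by the data.

Residual SDs were fixed once from the cohort moments the defaults
target: total-volume scatter of 80 (young) / 122 (older) cm³ makes the
normalized-volume SDs ≈ 0.6 / 0.93 cm³/(kg·m); the 5.5 mm² tendon
residual puts the young CSA~volume R² near 0.8; the 6 Nm torque
residual puts torque~body-size R² above 0.9. Stride-to-stride torque
variation defaults to 5% of the peak — a free parameter chosen as
typical for steady treadmill walking, not a reported value.
Anthropometry is rejection-sampled within ±4 SD to exclude
non-physical values. Random streams are split per subject and per
trial, so enlarging a cohort never perturbs previously generated
subjects.

The gait generator constructs the torque waveform first (a single
late-stance Gaussian peak at 45% of the cycle), then back-computes the
center of pressure that reproduces it under the same foot model the
inverse dynamics uses, with the foot held quasi-static. This makes
recovery a genuine round trip: at zero noise the mean peak is
reproduced to ~0.2% (the residual is filter attenuation), and at the
default noise to well under 5%.

### What passing tests do and do not show

The phantoms are ellipsoids and tubes, the trials have iid Gaussian
noise, hinge-like joints, and quasi-static feet. Passing tests
therefore demonstrate the correctness of the measurement chain —
volumetry arithmetic, geometry, pose/axis estimation, the
inverse-dynamics balance, the statistics — under the stated noise
models. They do not demonstrate robustness to realistic muscle shapes,
segmentation ambiguity at muscle boundaries, soft-tissue artifact
(correlated marker noise), out-of-plane joint motion, or force-plate
crosstalk, none of which the generator emulates.

## Numerical choices and degenerate inputs

- Pose fitting rejects collinear marker sets and mismatched
  correspondences; reflections are excluded by the determinant
  correction.
- The functional-axis fit requires a rotation span of at least 5°
  ("insufficient range of motion" otherwise); identity motion is
  rejected.
- A single-slice tendon has length 0, volume CSA × slice thickness, and
  its own slice as the mid-slice. A gap in the tendon label between the
  landmarks is an error naming the offending slices.
- Parallel line pairs fall back to the point-to-line distance in the
  moment-arm computation; intersecting lines give 0.
- The quadratic neutral fit needs ≥5 frames, ≥3 distinct angles, and an
  angle range that includes or brackets 0° within 5°.
- Holm rejects p-values outside [0, 1]; regressions reject constant x
  and n < 3; rank tests reject samples with n < 2.
- All conversions are centralized: mm for lengths, mm² CSA, cm³
  volumes, m and kg anthropometry; CSA is converted to cm² before
  forming CSA/volume ratios (cm⁻¹).

## Problem sizes

The shipped validation scripts and tests use: 5-muscle-set ellipsoid
phantoms at the 0.72 × 0.72 × 2 mm acquisition grid (plus halved and
doubled grids for the convergence study); 26-slice tendon tubes at 0°,
15°, and 30° incline; 91-frame range-of-motion sweeps from +20° to
-25°; 10-12-stride gait trials at 1,900 Hz force / 190 Hz marker
sampling; and 200 seeded cohort replicates for the power and
structure-detection rates. These sizes were chosen so each validation
is statistically meaningful while the whole suite stays quick to run.

## Known limitations

- Muscle phantoms are ellipsoids laid out without contact; real muscle
  boundaries and inter-muscle fascia are not modelled.
- CSA is axial-plane by design; for strongly inclined tendons the
  axial CSA overestimates the perpendicular CSA by $1/\cos\theta$.
- The planar inverse dynamics omits frontal/transverse moments and
  assumes a single force plate under the instrumented side.
- The exact rank-sum enumeration assumes no ties; tied data fall back
  to the corrected normal approximation even for small samples.
- Step length is stride/2 unless contralateral events are supplied;
  the generator currently emits ipsilateral events only.
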
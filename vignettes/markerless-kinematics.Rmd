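---
title: "Markerless gait kinematics with gaitkit: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait kinematics with gaitkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkit)
```

## The problem

Multi-camera markerless motion capture estimates 3D joint kinematics from
ordinary video: a 2D pose estimator locates joint keypoints in every camera
view, the rays are triangulated into 3D trajectories, and joint angles are
obtained by fitting an articulated skeletal model. Compared with
marker-based optoelectronic capture this removes markers from the athlete,
but introduces two characteristic error sources: per-frame pixel noise in
the 2D detections, and *systematic* offsets of detected keypoints relative
to true joint centers (deep-learning detectors inherit labeling biases of
tens of millimeters, largest at the knee and hip). gaitkit implements the
full analysis chain plus the concurrent-validation statistics used to
compare a markerless protocol against a marker-based reference, and — the
part that makes the package self-contained — a virtual-camera gait
simulator with exact ground truth, so every stage can be verified without
laboratory data.

## The simulator

`make_rig()` builds a converging circular rig (default: 8 cameras, 4 m
radius, 1.2 m height, 900 px focal length on a 1000x1000 image, roughly a
1-megapixel camera with a ~58 degree field of view). `generate_motion()`
produces walking-, running- or cycling-like trials: every degree of freedom
follows a sum of at most three harmonics of the cadence (default 1 Hz,
sampled at 30 Hz), so the true signals are band-limited well below the 6 Hz
filter cutoff and filtering is near-lossless on the truth. Contralateral
limbs run half a cycle out of phase and arms swing with the opposite leg.
Walking progresses back and forth (direction reversal half way, recorded
per cycle) with the excursion capped so the subject stays inside the
camera volume.

`observe_rig()` corrupts the exact projections with the error structure of
real 2D pose estimation:

* Gaussian pixel noise (`pixel_noise_sd`, default 0; study conditions use
  2 px);
* constant per-keypoint 3D offsets, expressed in the owning segment's frame
  by default so the bias travels with the limb like an anatomical
  mislabeling (a world-frame option exists for diagnostics); magnitudes are
  capped at 0.1 m, with 0.01-0.05 m the realistic range;
* scheduled per-camera occlusions (confidence forced to 0);
* a confidence model `clamp(1 - pixel_error / 20 px, 0, 1)` — monotone,
  bounded, and invertible, which makes it convenient to test against.

A parallel marker-based reference channel
(`generate_reference_markers()`) emits anatomical landmarks (malleoli,
epicondyles, styloids, pelvis landmarks) and thigh cluster markers that
follow the segments rigidly, plus i.i.d. Gaussian "soft-tissue" noise
(default 5 mm). Landmark-pair midpoints coincide with true joint centers by
construction; hip centers are recovered with a functional sphere-fit
method. The simulator does **not** model skin deformation, marker
occlusion, lens distortion, rolling shutter, or pose-estimator outliers
with non-Gaussian tails — passing tests therefore demonstrate correctness
of the algorithms under the stated error structure, not performance on any
particular real camera system.

## Triangulation

`triangulate_point()` solves the homogeneous DLT system with each camera's
two rows multiplied by its detection confidence (linear weighting; squared
selectable via `weight_power`). `robust_triangulate()` then iteratively
drops the camera with the largest reprojection residual while the mean
residual exceeds `max_reproj_error` and more than two cameras remain; ties
are broken toward the lower-confidence camera, then the lower index, so
results are deterministic. Defaults: `min_confidence = 0.3` admits a
detection (drops occluded and near-zero detections); `max_reproj_error =
15` px on a 1000 px image separates the ~2 px noise regime from gross
mislocalizations by an order of magnitude. Both are pipeline-config
settings so calibrated values can be substituted. Interior gaps of up to
`max_gap = 5` frames are filled linearly; longer gaps stay invalid rather
than inventing data.

## Filtering, events, cycles

`butterworth_lowpass()` applies a 4th-order 6 Hz low-pass Butterworth
filter, by default as a zero-lag forward-backward pass with odd reflection
padding. Because two passes halve the bandwidth, the per-pass cutoff is
pre-warped (solved numerically on the digital response) so the cascade's
-3 dB point lands exactly on the nominal cutoff; DC gain is exactly 1. A
zero-lag filter is used because the downstream agreement statistics are
phase-sensitive; the single-pass causal variant is selectable
(`zero_phase = FALSE`).

Heel strikes are detected with the coordinate-based method: local maxima of
the heel's position relative to the sacrum along the progression axis, in
the direction of travel, with a minimum peak separation of half the nominal
stride time (known from the metronome cadence) to reject double peaks.
Candidates at a direction reversal are turning artifacts and are excluded.
Cycling has no heel strikes; cycles are segmented at the peaks of the
ankle's vertical position (a crank-angle proxy). Each cycle is linearly
time-warped to 101 samples (0-100% in 1% steps, the field's convention —
`normalized_length` is configurable).

`resample_signal()` uses Fourier-domain resampling (spectrum truncation /
zero-padding with symmetric Nyquist-bin handling), which is exact for
band-limited content and makes up/down round trips the identity.

## The skeletal model and inverse kinematics

The shipped `default_model()` is a simplified full-body humanoid: pelvis
root (free translation and orientation), a five-link lumbar stack, torso,
head, and three-segment limbs, with 25 generalized coordinates. The
constraint set is:

* wrist flexion and deviation locked at 0 degrees, forearm
  pronation/supination locked at 90 degrees (no keypoint can observe them);
* hip flexion limited to 150 degrees (enough for pedaling), other
  coordinates carry generous physiological bounds;
* subtalar angles unlocked;
* knee abduction/adduction and internal/external rotation coupled to knee
  flexion by piecewise-linear splines that vanish at full extension — the
  coupling knots are model data and can be replaced from a model file;
* each lumbar vertebra carries one fifth of the total lumbar flexion (a
  single `lumbar_flexion` coordinate drives five coupled joints); the
  uniform 1/5 split is the simplest faithful reading of a chained-vertebra
  constraint and is likewise replaceable.

Keypoint placements cover a 21-point body layout (eyes and ears excluded).
`scale_model()` performs measurement-based scaling: per-segment factors are
ratios of experimental to model inter-keypoint distances from one static
frame (T-pose), averaged when several pairs map to a segment, inherited
from the parent where no pair is configured.

`inverse_kinematics_frame()` minimizes the weighted sum of squared
keypoint distances subject to the locks, limits and couplings. Locked and
coupled DOFs are eliminated from the parameterization (so they hold
*exactly*), and limits are box bounds in a Levenberg-Marquardt solver
(`minpack.lm::nls.lm`, max 200 iterations, objective tolerance 1e-8, all
config-exposed) with an analytic chain-rule Jacobian (rotation axes crossed
with lever arms, plus coupling slopes). Default keypoint weights are 1,
except Nose/Head 0.1 and shoulders/hips 2. Zero-angle priors (weight 1 on
pelvis list, pelvis tilt, lumbar flexion and the ankle angles) apply only
to static scaling solves, where the subject is known to stand upright;
dynamic frames use keypoint terms alone. Sequences warm-start each frame
from the previous solution.

### An identifiability caveat

With only two pelvis keypoints and a free pelvis translation, pelvis tilt,
lumbar flexion and hip flexion form a *near*-gauge direction: a tilt error
compensated by opposite lumbar and hip corrections moves the torso
keypoints by only ~0.1 m x (tilt error in radians). With 2 px pixel noise
this lets hip flexion wander by ~2 degrees even when knee and ankle errors
are a fraction of a degree. This is the same spine-curvature (lordotic vs
kyphotic) ambiguity that markerless pipelines exhibit on real data, and it
is why accuracy summaries in this package pool errors across the sagittal
lower-limb angles rather than reporting the hip alone as representative.

### Systematic-offset compensation

Constant segment-frame keypoint offsets cannot be fixed by per-frame
optimization alone — they excite the gauge direction above. The remedy
mirrors laboratory practice: `estimate_placement_offsets()` averages, over
a trial, the residual between triangulated keypoints and the model
keypoints of a reference solve (e.g. inverse kinematics on marker-derived
joint centers), expressed in each segment's frame; the estimates are then
baked into the model with `apply_placement_offsets()`, after which the
model *expects* the biased locations. With compensation, constrained IK
under 3-5 cm hip/knee offsets is more accurate than model-free
segment-vector angles computed from the same trajectories — the property
the package's mitigation test checks over 20 seeds.

## Agreement statistics

`cmc_interprotocol()` implements the two-protocol coefficient of multiple
correlation: with protocols $p$, cycles $g$, normalized frames $f$,

$$\mathrm{CMC} = \sqrt{1 -
  \frac{\sum_{g,p,f}(Y_{pgf}-\bar Y_{gf})^2 / (G F (P-1))}
       {\sum_{g,p,f}(Y_{pgf}-\bar Y_{g})^2 / (G (P F - 1))}}$$

jointly sensitive to correlation, gain and offset: 1 for overlapping
curves, and complex — reported as `NaN` and classified "none" — when the
inter-protocol offset exceeds the grand mean range of motion (negative
radicand). The normalization constants are unit-tested against brute-force
evaluation of the sums. Classification bands: poor < 0.75, good
0.75-0.84, very good 0.85-0.94, excellent >= 0.95.

ROM (gain) errors are per-cycle max-min differences between protocols,
Shapiro-Wilk-checked for normality, then paired-t-tested at the 5% level.
`bland_altman()` pools differences over cycles and frames: bias = mean
difference, limits of agreement = bias +/- 1.96 sd (the interval expected
to contain 95% of differences under normality). Normality is checked on
the per-cycle mean differences — the paired means are taken per cycle
because the cycle is the experimental repetition unit; pooled points would
be heavily autocorrelated. Heteroscedasticity is declared when |difference|
correlates with the paired means at the 5% level (the concept has no
canonical test; the rule is config-exposed). `summarize_agreement()` runs
everything per angle and emits a long-format table; per-angle degeneracies
(zero variance, too few cycles) become flagged rows, never failures.

## Numerical choices and degenerate inputs

* Angles are degrees at every public interface and radians internally;
  lengths are meters; the world frame is right-handed, Y-up.
* Triangulation with fewer than two usable rays yields an invalid point
  (flagged), not an exception; IK frames with fewer than three valid
  keypoints are flagged invalid and keep the previous pose.
* The sphere fit in `functional_joint_center()` is the algebraic
  least-squares formulation; rank-deficient paths (planar arcs) fall back
  to the minimum-norm solution and flag the unconstrained axis; static
  markers are a hard error.
* Identical-and-constant protocols give CMC 1 flagged "degenerate";
  zero-variance Shapiro/t-tests are short-circuited to p = 1.
* Filter inputs must exceed three filter orders in length (reflection
  padding needs context); shorter inputs error explicitly.

## Problem sizes used by the test-suite and validation runs

Simulated trials use 2-8 gait cycles at 30 Hz (60-240 frames, 8 cameras,
21 keypoints); the statistical identities use 10^5 samples
(limits-of-agreement coverage) and 1000 randomized waveform toys (complex-
CMC pathology); the mitigation property uses 20 seeded replicates of a
3-cycle trial. These sizes give stable statistics while keeping a full run
of the suite comfortably interactive.

## Known limitations

* The simulator's error model is Gaussian plus constant offsets; real pose
  estimators produce occasional gross outliers with heavy tails (the
  robust exclusion handles these, but the default tests do not emphasize
  them).
* Single subject, single person per scene; no multi-person association.
* No muscles, no dynamics, no real-time operation; no RANSAC triangulation
  or Kalman smoothing.
* Model files use YAML (TOML is the other common choice for this kind of
  tool; YAML was chosen because a mature parser is universally available
  to R).
* The hip-flexion identifiability caveat above applies to any keypoint set
  without mid-pelvis or sacrum detections.
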
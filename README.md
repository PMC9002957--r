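# gaitkit

Markerless multi-camera gait kinematics in R: confidence-weighted robust
triangulation of 2D joint keypoints, zero-lag Butterworth filtering,
coordinate-based gait event detection, measurement-based scaling and
constrained inverse kinematics on an articulated skeletal model, and the
concurrent-validation statistics used to compare a markerless protocol
against a marker-based reference. A built-in virtual-camera gait simulator
with exact ground truth makes every stage testable without laboratory data.

**Who it is for.** Biomechanists and sports scientists analyzing human
movement from multiple calibrated RGB cameras (OpenPose-style 2D keypoint
detections), and methodologists who need a reference implementation of the
agreement statistics (inter-protocol CMC, Bland-Altman limits of agreement,
ROM error tests) used in concurrent-validity studies.

## The methods at the core

* **Weighted robust DLT triangulation.** Each camera contributes the two
  homogeneous rows `u p3 - p1` and `v p3 - p2` of its projection matrix,
  multiplied by the detection confidence; the 3D point is the smallest
  right singular vector. Cameras are dropped greedily while the mean
  reprojection residual exceeds a threshold (default 15 px) and more than
  two remain.
* **Constrained inverse kinematics.** Per frame, minimize
  `sum_i w_i ||x_i^exp - x_i^model(q)||^2` over the generalized coordinates
  `q`, subject to joint locks (wrist flexion/deviation = 0, forearm
  pronation/supination = 90 deg), limits (hip flexion <= 150 deg), and
  couplings (knee frontal/transverse angles driven by knee flexion, five
  lumbar vertebrae sharing one flexion coordinate). Solved by bounded
  Levenberg-Marquardt with an analytic chain-rule Jacobian; locked and
  coupled DOFs are eliminated so constraints hold exactly.
* **Inter-protocol CMC.** For protocols `p = 1..P` (P = 2), cycles
  `g = 1..G`, normalized frames `f = 1..F`:

  ```
  CMC = sqrt( 1 - [ sum (Y_pgf - Ybar_gf)^2 / (G F (P-1)) ]
                / [ sum (Y_pgf - Ybar_g)^2  / (G (P F - 1)) ] )
  ```

  1 for overlapping curves; complex (reported `NaN`) when the
  inter-protocol offset exceeds the grand mean ROM.
* **Bland-Altman.** Bias = mean paired difference; limits of agreement =
  bias +/- 1.96 sd — the interval expected to contain 95% of differences.

## Worked example

Simulate an eight-cycle walking trial seen by eight virtual cameras with
2 px detection noise, run the full pipeline (triangulate → filter → events
→ scale → IK → angles → agreement against the ground-truth channel), and
read the per-angle agreement table:

```r
library(gaitkit)
sim <- simulate_trial("demo",
  spec    = motion_spec("walking", cadence = 1, n_cycles = 8, seed = 11),
  corrupt = corruption_spec(pixel_noise_sd = 2, seed = 12))
res <- run_pipeline(sim$config)
res$agreement[, c("angle", "cmc", "cmc_class", "pearson_r",
                  "rom_err_mean", "mean_err", "rmse")]
```

The run logs each stage and prints (abridged):

```
[INFO] triangulate: valid 5040/5040, mean cameras used 8, mean residual 2.263 px
[INFO] events: 8 cycles detected
[INFO] ik: marker RMSE range [0.0022, 0.0049] m (best practice: below 0.02-0.04 m)

           angle   cmc cmc_class pearson_r rom_err_mean mean_err  rmse
   hip_flexion_r 0.996 excellent     0.992        1.402   0.0422 2.334
 hip_adduction_r 0.996 excellent     0.993        0.667  -0.0607 0.342
  hip_rotation_r 0.983 excellent     0.968        0.833  -0.1242 0.897
  knee_flexion_r 0.999 excellent     0.999       -0.263  -0.6202 0.847
 ankle_flexion_r 0.993 excellent     0.995        0.547  -0.9071 1.092
      subtalar_r 0.880 very good     0.798        3.885   0.4818 2.079
```

Reading it: every per-frame marker RMSE is a few millimeters, far inside
the 2-4 cm best-practice band for model fit; the sagittal angle waveforms
(hip/knee/ankle flexion) agree with ground truth at CMC >= 0.99
("excellent"), with sub-degree mean errors and RMS errors of 1-2 degrees;
the small subtalar angle, whose range of motion is only a few degrees, is
the least well resolved — exactly the ordering reported for markerless
systems on real data.

All outputs are also written as files (`keypoints3d.trc`,
`angles.mot`, `cycles.csv`, `agreement.csv`, `pipeline.log`) that re-parse
with the package's own readers. A command-line front end covering the same
verbs is installed as `exec/gaitkit` (`simulate`, `triangulate`, `filter`,
`events`, `scale`, `ik`, `agree`, `run`).

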
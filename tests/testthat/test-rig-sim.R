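# Virtual camera rig, motion generator, observation corruption and the
# marker-based reference channel.

test_that("make_rig places cameras evenly and aims them at the target", {
  rig <- make_rig(8, radius = 4, target = c(0, 1, 0))
  expect_length(rig, 8)
  for (cm in rig) {
    expect_lt(max(abs(crossprod(cm$rotation) - diag(3))), 1e-10)
    expect_equal(det(cm$rotation), 1, tolerance = 1e-10)
    pos <- gaitkit:::camera_position(cm)
    expect_equal(sqrt(sum((pos - c(0, cm$focal[1] * 0, 0))[c(1, 3)]^2)), 4,
                 tolerance = 1e-10)
    # optical axis passes through the target: target projects to the center
    p <- project_point(c(0, 1, 0), cm)
    expect_equal(as.numeric(p), as.numeric(cm$center), tolerance = 1e-8)
  }
  # 45 degree spacing
  angs <- sort(vapply(rig, function(cm) {
    pos <- gaitkit:::camera_position(cm)
    atan2(pos[3], pos[1])
  }, numeric(1)))
  expect_equal(diff(angs), rep(pi / 4, 7), tolerance = 1e-10)

  two <- make_rig(2, radius = 3, heights = 1, target = c(0, 1, 0))
  z1 <- two[[1]]$rotation[3, ]; z2 <- two[[2]]$rotation[3, ]
  expect_equal(as.numeric(z1 + z2), c(0, 0, 0), tolerance = 1e-10)

  expect_error(make_rig(1, 4), "at least 2 cameras")
})

test_that("pinhole projection follows similar triangles and flags views", {
  cam <- camera_params(focal = c(1000, 1000), center = c(500, 500),
                       rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(as.numeric(project_point(c(0, 0, 1), cam)), c(500, 500))
  expect_equal(as.numeric(project_point(c(0.1, 0, 1), cam)), c(600, 500))
  behind <- project_point(c(0, 0, -1), cam)
  expect_true(attr(behind, "out_of_view"))
  expect_error(project_point(c(0, 0, 0), cam), "camera center")
})

test_that("generated motion has the requested cycles, events and period", {
  spec <- motion_spec("walking", cadence = 1, n_cycles = 8, frame_rate = 30,
                      seed = 3)
  truth <- generate_motion(spec, fx_model())
  expect_equal(nrow(truth$angles), 240)
  expect_length(truth$event_frames, 8)
  # knee flexion amplitude override stays within the requested band
  spec2 <- motion_spec("walking", cadence = 1, n_cycles = 2,
                       angle_amplitudes = list(knee_flexion_r = 30),
                       angle_offsets = c(knee_flexion_r = 30))
  k <- generate_motion(spec2, fx_model())$angles[, "knee_flexion_r"]
  expect_gte(min(k), 0); expect_lte(max(k), 60)
  # periodicity: autocorrelation of a DOF peaks at the cadence period
  x <- truth$angles[, "hip_flexion_r"]
  ac <- stats::acf(x, lag.max = 45, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[20:45]) + 19, 30, tolerance = 1)
  # determinism
  expect_identical(generate_motion(spec, fx_model()),
                   generate_motion(spec, fx_model()))
})

test_that("amplitudes pushing a DOF past its limit abort with the DOF name", {
  spec <- motion_spec("walking", n_cycles = 1,
                      angle_offsets = c(hip_flexion_r = 145),
                      angle_amplitudes = list(hip_flexion_r = 30))
  expect_error(generate_motion(spec, fx_model()), "hip_flexion_r")
})

test_that("clean observations are exact projections with confidence 1", {
  obs <- fx_walk2_obs_clean()
  truth <- fx_walk2()
  expect_true(all(obs$conf %in% c(0, 1)))
  expect_gt(mean(obs$conf == 1), 0.99)   # nearly everything in view
  t0 <- 10; k0 <- which(obs$keypoints == "RKnee"); c0 <- 3
  p <- project_point(truth$keypoints[t0, "RKnee", ], fx_rig()[[c0]])
  expect_equal(c(obs$u[t0, c0, k0], obs$v[t0, c0, k0]), as.numeric(p),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a constant world-frame offset passes through triangulation intact", {
  truth <- fx_walk2()
  off <- c(0, 0.03, 0)
  obs <- observe_rig(truth, fx_rig(),
                     corruption_spec(systematic_offsets = list(RHip = off),
                                     offset_frame = "world"))
  traj <- triangulate_sequence(obs, fx_rig())
  d <- traj$pos[, "RHip", ] - truth$keypoints[, "RHip", ]
  for (t in seq_len(nrow(d)))
    expect_equal(as.numeric(d[t, ]), off, tolerance = 1e-8)
  # other keypoints untouched
  expect_lt(max(abs(traj$pos[, "RKnee", ] - truth$keypoints[, "RKnee", ])),
            1e-8)
})

test_that("segment-frame offsets travel with the limb", {
  truth <- fx_walk2()
  off <- c(0.03, 0, 0)
  obs <- observe_rig(truth, fx_rig(),
                     corruption_spec(systematic_offsets = list(RKnee = off)))
  traj <- triangulate_sequence(obs, fx_rig())
  d <- traj$pos[, "RKnee", ] - truth$keypoints[, "RKnee", ]
  # magnitude constant, direction rotating with the femur
  mags <- sqrt(rowSums(d^2))
  expect_equal(mags, rep(0.03, length(mags)), tolerance = 1e-8)
  for (t in c(1, 20, 40)) {
    expected <- as.numeric(truth$seg_rot[["femur_r"]][, , t] %*% off)
    expect_equal(as.numeric(d[t, ]), expected, tolerance = 1e-8)
  }
})

test_that("occlusions zero confidence for the scheduled cameras and frames", {
  truth <- fx_walk2()
  occ <- do.call(rbind, lapply(1:6, function(cc)
    data.frame(camera = cc, keypoint = "RAnkle", from = 10, to = 20)))
  obs <- observe_rig(truth, fx_rig(), corruption_spec(occlusions = occ))
  k <- which(obs$keypoints == "RAnkle")
  expect_true(all(obs$conf[10:20, 1:6, k] == 0))
  expect_true(all(obs$conf[10:20, 7:8, k] == 1))
  expect_true(all(obs$conf[9, 1:6, k] == 1))
})

test_that("identical corruption seeds give bit-identical observations", {
  truth <- fx_walk2()
  mk <- function() observe_rig(truth, fx_rig(),
                               corruption_spec(pixel_noise_sd = 3, seed = 42))
  expect_identical(mk(), mk())
})

test_that("reference marker midpoints coincide with true joint centers", {
  truth <- fx_walk2()
  mk <- generate_reference_markers(truth, soft_tissue_sd = 0)
  mid <- (mk$pos[, "RAnkleMed", ] + mk$pos[, "RAnkleLat", ]) / 2
  expect_lt(max(abs(mid - truth$keypoints[, "RAnkle", ])), 1e-12)
  mid_k <- (mk$pos[, "LKneeMed", ] + mk$pos[, "LKneeLat", ]) / 2
  expect_lt(max(abs(mid_k - truth$keypoints[, "LKnee", ])), 1e-12)
})

test_that("soft-tissue noise on a landmark pair averages down by sqrt(2)", {
  truth <- generate_motion(motion_spec("walking", n_cycles = 8, seed = 5),
                           fx_model())
  sdv <- 0.005
  mk <- generate_reference_markers(truth, soft_tissue_sd = sdv, seed = 9)
  clean <- generate_reference_markers(truth, soft_tissue_sd = 0)
  mid_err <- (mk$pos[, "RAnkleMed", ] + mk$pos[, "RAnkleLat", ]) / 2 -
    (clean$pos[, "RAnkleMed", ] + clean$pos[, "RAnkleLat", ]) / 2
  expect_equal(apply(mid_err, 2, sd), rep(sdv / sqrt(2), 3),
               tolerance = 0.25, ignore_attr = TRUE)
})

test_that("functional method recovers a hip center from rotating markers", {
  truth <- fx_walk2()
  mk <- generate_reference_markers(truth, soft_tissue_sd = 0)
  jc <- marker_joint_centers(mk)
  expect_lt(max(abs(jc[, "RHip", ] - truth$keypoints[, "RHip", ])), 2e-3)
  expect_lt(max(abs(jc[, "RKnee", ] - truth$keypoints[, "RKnee", ])), 1e-12)
})
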
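# Skeletal model: forward kinematics, scaling, constrained IK, functional
# joint centers, joint-angle extraction.

test_that("neutral-pose keypoints sit at their reference placements", {
  model <- fx_model()
  q <- neutral_pose(model, pelvis_height = 0)
  kp <- forward_kinematics(model, q)
  expect_equal(as.numeric(kp["RHip", ]), c(0, -0.07, 0.09), tolerance = 1e-12)
  expect_equal(as.numeric(kp["RKnee", ]), c(0, -0.49, 0.09), tolerance = 1e-12)
  expect_equal(as.numeric(kp["RAnkle", ]), c(0, -0.92, 0.09), tolerance = 1e-12)
})

test_that("single-joint and composed rotations move keypoints as expected", {
  model <- fx_model()
  q <- neutral_pose(model, 0)
  q["knee_flexion_r"] <- 90
  kp <- forward_kinematics(model, q)
  # ankle swings straight behind the knee at 90 deg flexion (coupled knee
  # rotations displace it slightly out of plane)
  knee <- kp["RKnee", ]; ankle <- kp["RAnkle", ]
  v <- ankle - knee
  expect_equal(as.numeric(v[1]), -0.43, tolerance = 0.02)
  expect_equal(as.numeric(v[2]), 0, tolerance = 0.02)
  # two-link chain: hip 45 + knee 45 about the same axis give 90 total
  m2 <- fx_model()
  m2$couplings$knee_adduction_r$y <- c(0, 0, 0)
  m2$couplings$knee_rotation_r$y <- c(0, 0, 0)
  m2 <- skeletal_model(m2$segments, m2$dofs, m2$placements, m2$markers,
                       m2$couplings, m2$measurement_pairs)
  q2 <- neutral_pose(m2, 0)
  q2["hip_flexion_r"] <- 45
  kp2 <- forward_kinematics(m2, q2)
  thigh_dir <- (kp2["RKnee", ] - kp2["RHip", ]) / 0.42
  expect_equal(as.numeric(thigh_dir), c(sin(pi / 4), -cos(pi / 4), 0),
               tolerance = 1e-10)
  q2["knee_flexion_r"] <- -45  # knee axis is reversed: -45 adds to hip's 45
  kp3 <- forward_kinematics(m2, q2)
  shank_dir <- (kp3["RAnkle", ] - kp3["RKnee", ]) / 0.43
  expect_equal(as.numeric(shank_dir), c(1, 0, 0), tolerance = 1e-10)
})

test_that("measurement-based scaling is exact arithmetic on distances", {
  model <- fx_model()
  ref <- forward_kinematics(model, neutral_pose(model))
  # identity: measured = model
  res <- scale_model(model, ref)
  expect_equal(unname(res$scales), rep(1, length(res$scales)),
               tolerance = 1e-12)
  # a 10% longer thigh distance gives femur scale 1.10
  mod <- ref
  v <- mod["RKnee", ] - mod["RHip", ]
  mod["RKnee", ] <- mod["RHip", ] + 1.10 * v
  res2 <- scale_model(model, mod)
  expect_equal(unname(res2$scales["femur_r"]), 1.10, tolerance = 1e-10)
})

test_that("scaling recovers a uniformly enlarged subject", {
  model <- fx_model()
  sm <- model$segments
  sm[, c("ox", "oy", "oz")] <- sm[, c("ox", "oy", "oz")] * 1.05
  pl <- model$placements
  pl[, c("lx", "ly", "lz")] <- pl[, c("lx", "ly", "lz")] * 1.05
  big <- skeletal_model(sm, model$dofs, pl, model$markers,
                        model$couplings, model$measurement_pairs)
  static_kp <- forward_kinematics(big, neutral_pose(big, 1.05))
  res <- scale_model(model, static_kp)
  expect_equal(unname(res$scales), rep(1.05, length(res$scales)),
               tolerance = 1e-6)
  # scaled model reproduces the static keypoints
  kp <- forward_kinematics(res$model, neutral_pose(res$model, 1.05))
  expect_lt(max(abs(kp - static_kp)), 1e-9)
})

test_that("IK inverts forward kinematics on feasible poses", {
  model <- fx_model()
  q <- neutral_pose(model)
  q[c("hip_flexion_r", "knee_flexion_r", "ankle_flexion_r")] <- c(35, 40, -10)
  q[c("hip_adduction_r", "hip_rotation_r")] <- c(8, -12)
  q["pelvis_tilt"] <- 6; q["lumbar_flexion"] <- 12
  q[c("shoulder_flexion_l", "elbow_flexion_l")] <- c(-20, 45)
  target <- forward_kinematics(model, q)
  sol <- inverse_kinematics_frame(model, target, q_init = neutral_pose(model))
  expect_true(sol$valid)
  expect_lt(sol$rmse, 1e-6)
  expect_lt(max(abs(sol$q - q[names(sol$q)])), 0.1)
})

test_that("limits clamp: demanding 160 deg hip flexion returns 150", {
  model <- fx_model()
  q <- neutral_pose(model)
  q["hip_flexion_r"] <- 160; q["knee_flexion_r"] <- 40
  target <- forward_kinematics(model, q)
  sol <- inverse_kinematics_frame(model, target)
  expect_lte(sol$q[["hip_flexion_r"]], 150 + 1e-9)
  expect_gt(sol$q[["hip_flexion_r"]], 145)
  expect_gt(sol$rmse, 0)
})

test_that("locks hold exactly in every solved pose", {
  model <- fx_model()
  truth <- fx_walk2()
  ik <- inverse_kinematics_sequence(model, truth$keypoints[1:10, , ])
  a <- compute_joint_angles(model, ik,
                            angles = c("pro_sup_r", "pro_sup_l",
                                       "wrist_flexion_r", "wrist_deviation_l"))
  expect_true(all(a[, "pro_sup_r"] == 90))
  expect_true(all(a[, "pro_sup_l"] == 90))
  expect_true(all(a[, "wrist_flexion_r"] == 0))
  expect_true(all(a[, "wrist_deviation_l"] == 0))
  # limited coordinates never leave their bounds
  b <- gaitkit:::coordinate_bounds(model)
  for (nm in colnames(ik$q)) {
    expect_gte(min(ik$q[, nm]), b$lo[[nm]] - 1e-9)
    expect_lte(max(ik$q[, nm]), b$hi[[nm]] + 1e-9)
  }
})

test_that("IK objective is non-increasing and warm starts stay continuous", {
  model <- fx_model()
  truth <- fx_walk2()
  sol <- inverse_kinematics_frame(model, truth$keypoints[15, , ])
  expect_true(all(diff(sol$objective_trace) <= 1e-12))
  ik <- inverse_kinematics_sequence(model, truth$keypoints[1:20, , ])
  jumps <- apply(abs(diff(ik$q[5:20, ])), 2, max)
  truth_jumps <- apply(abs(diff(truth$angles[5:20, colnames(ik$q)])), 2, max)
  expect_true(all(jumps <= pmax(3 * truth_jumps, 0.5)))
})

test_that("fewer than three valid keypoints marks the frame invalid", {
  model <- fx_model()
  kp <- forward_kinematics(model, neutral_pose(model))
  kp[4:nrow(kp), ] <- NA
  sol <- inverse_kinematics_frame(model, kp[1:5, ])
  expect_true(sol$valid)   # 3 valid keypoints is the minimum
  kp[3, ] <- NA
  sol2 <- inverse_kinematics_frame(model, kp[1:5, ])
  expect_false(sol2$valid)
})

test_that("sphere fitting recovers centers and flags degeneracy", {
  th <- seq(0, 4 * pi, length.out = 60)
  ph <- seq(0.2, 2.5, length.out = 60)
  X <- cbind(0.1 + 0.3 * sin(ph) * cos(th),
             0.9 + 0.3 * sin(ph) * sin(th),
             0.3 * cos(ph))
  fit <- functional_joint_center(X)
  expect_equal(fit$center, c(0.1, 0.9, 0), tolerance = 1e-9)
  expect_equal(fit$radii, 0.3, tolerance = 1e-9)
  # planar arc: in-plane center recovered, out-of-plane axis flagged
  arc <- cbind(0.2 + 0.25 * cos(th), 0.5 + 0.25 * sin(th), 0.7)
  fit2 <- functional_joint_center(arc)
  expect_equal(fit2$center[1:2], c(0.2, 0.5), tolerance = 1e-6)
  expect_true(fit2$low_confidence_axis[3])
  # static markers are degenerate
  expect_error(functional_joint_center(matrix(1, 20, 3)), "degenerate")
})

test_that("joint-angle extraction honors couplings and locks", {
  model <- fx_model()
  Q <- matrix(0, 5, length(coordinate_names(model)),
              dimnames = list(NULL, coordinate_names(model)))
  Q[, "hip_flexion_r"] <- 20
  Q[, "knee_flexion_r"] <- c(0, 30, 60, 90, 120)
  a <- compute_joint_angles(model, Q,
                            angles = c("hip_flexion_r", "knee_adduction_r",
                                       "knee_rotation_r", "pro_sup_r"))
  expect_equal(a[, "hip_flexion_r"], rep(20, 5))
  expect_equal(a[, "knee_adduction_r"],
               coupling_value(model, "knee_adduction_r", Q[, "knee_flexion_r"]))
  expect_equal(a[1, "knee_adduction_r"], 0,
               ignore_attr = TRUE)   # zero at full extension
  expect_equal(a[, "pro_sup_r"], rep(90, 5))
  expect_error(compute_joint_angles(model, Q, angles = "no_such_angle"),
               "unknown angle")
})

test_that("direct segment-vector angles match truth on clean keypoints", {
  truth <- fx_walk2()
  da <- direct_segment_angles(fx_model(), truth$keypoints)
  # hip direct angle includes pelvis tilt; knee and ankle are tight
  expect_lt(mean(abs(da[, "knee_flexion"] -
                       truth$angles[, "knee_flexion_r"])), 0.5)
  expect_lt(mean(abs(da[, "ankle_flexion"] -
                       truth$angles[, "ankle_flexion_r"])), 1.5)
  expect_lt(mean(abs(da[, "hip_flexion"] -
                       truth$angles[, "hip_flexion_r"])), 6)
})
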
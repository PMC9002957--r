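# Confidence-weighted robust DLT triangulation.

test_that("noiseless two-camera observations triangulate exactly", {
  rig <- fx_rig()
  x <- c(0.1, 1.2, 0.3)
  uv <- project_all(x, rig)
  sol <- triangulate_point(uv[1:2, ], c(1, 1), rig[1:2])
  expect_true(sol$valid)
  expect_lt(max(abs(sol$position - x)), 1e-9)
  expect_lt(max(sol$residuals[1:2]), 1e-6)
})

test_that("confidence weighting pulls the estimate toward reliable rays", {
  rig <- fx_rig()[c(1, 3)]
  x <- c(0.2, 1.0, -0.1)
  uv <- project_all(x, rig)
  uv[1, ] <- uv[1, ] + c(12, -9)        # noise only on the first camera
  weighted <- triangulate_point(uv, c(0.31, 1), rig)
  unweighted <- oracle_dlt(uv, rig)
  expect_lt(sqrt(sum((weighted$position - x)^2)),
            sqrt(sum((unweighted - x)^2)))
})

test_that("fewer than two usable observations yields an invalid point", {
  rig <- fx_rig()
  uv <- project_all(c(0, 1, 0), rig)
  sol <- triangulate_point(uv, c(1, rep(0, 7)), rig)
  expect_false(sol$valid)
  expect_true(all(is.na(sol$position)))
  # below min_confidence does not count as usable
  sol2 <- triangulate_point(uv, c(1, 0.1, rep(0, 6)), rig,
                            min_confidence = 0.3)
  expect_false(sol2$valid)
})

test_that("robust triangulation excludes a grossly corrupted camera", {
  rig <- fx_rig()
  set.seed(101)
  for (rep in 1:20) {
    x <- random_point()
    uv <- project_all(x, rig)
    bad <- sample(8, 1)
    uv[bad, ] <- uv[bad, ] + c(100, 0)
    sol <- robust_triangulate(uv, rep(1, 8), rig, max_reproj_error = 15)
    expect_false(sol$used[bad])
    expect_equal(sol$n_cameras_used, 7L)
    oracle <- oracle_dlt(uv, rig, use = setdiff(1:8, bad))
    expect_lt(max(abs(sol$position - oracle)), 1e-6)
  }
})

test_that("consistent cameras are a fixed point of the exclusion loop", {
  rig <- fx_rig()
  x <- c(-0.3, 1.4, 0.2)
  uv <- project_all(x, rig)
  plain <- triangulate_point(uv, rep(1, 8), rig)
  rob <- robust_triangulate(uv, rep(1, 8), rig)
  expect_equal(rob$position, plain$position, tolerance = 1e-12)
  expect_equal(rob$n_cameras_used, 8L)
  expect_false(rob$low_quality)
})

test_that("mutually inconsistent views terminate at two cameras, flagged", {
  rig <- fx_rig()[c(1, 4, 7)]
  x <- c(0, 1, 0)
  uv <- project_all(x, rig)
  uv[1, ] <- uv[1, ] + c(60, 0)
  uv[2, ] <- uv[2, ] + c(-80, 30)
  sol <- robust_triangulate(uv, rep(1, 3), rig, max_reproj_error = 0.5)
  expect_equal(sol$n_cameras_used, 2L)
  expect_true(sol$low_quality)
})

test_that("occluded frames fall back to the surviving cameras", {
  truth <- fx_walk2()
  occ <- do.call(rbind, lapply(1:6, function(cc)
    data.frame(camera = cc, keypoint = "RAnkle", from = 10, to = 20)))
  obs <- observe_rig(truth, fx_rig(), corruption_spec(occlusions = occ))
  traj <- triangulate_sequence(obs, fx_rig())
  expect_true(all(traj$valid[10:20, "RAnkle"]))
  expect_true(all(traj$n_cameras_used[10:20, "RAnkle"] == 2))
  expect_lt(max(abs(traj$pos[10:20, "RAnkle", ] -
                      truth$keypoints[10:20, "RAnkle", ])), 1e-8)
})

test_that("interior gaps up to max_gap are filled on the chord", {
  truth <- fx_walk2()
  occ <- do.call(rbind, lapply(1:8, function(cc)
    data.frame(camera = cc, keypoint = "LWrist", from = 15, to = 17)))
  obs <- observe_rig(truth, fx_rig(), corruption_spec(occlusions = occ))
  traj <- triangulate_sequence(obs, fx_rig(), max_gap = 5)
  expect_true(all(traj$valid[15:17, "LWrist"]))
  expect_true(all(traj$interpolated[15:17, "LWrist"]))
  for (d in 1:3) {
    chord <- approx(c(14, 18), traj$pos[c(14, 18), "LWrist", d], xout = 15:17)$y
    expect_equal(as.numeric(traj$pos[15:17, "LWrist", d]), chord,
                 tolerance = 1e-12)
  }
  # longer gaps stay invalid
  occ2 <- do.call(rbind, lapply(1:8, function(cc)
    data.frame(camera = cc, keypoint = "LWrist", from = 15, to = 24)))
  obs2 <- observe_rig(truth, fx_rig(), corruption_spec(occlusions = occ2))
  traj2 <- triangulate_sequence(obs2, fx_rig(), max_gap = 5)
  expect_false(any(traj2$valid[15:24, "LWrist"]))
})

test_that("mean 3D error does not increase with more uncorrupted cameras", {
  rig <- fx_rig()
  err_by_n <- sapply(c(2, 4, 8), function(ncam) {
    errs <- vapply(seq_len(100), function(s) {
      set.seed(1000 + s)
      x <- random_point()
      uv <- project_all(x, rig)[seq_len(ncam), , drop = FALSE] +
        matrix(rnorm(2 * ncam, 0, 2), ncam, 2)
      sol <- triangulate_point(uv, rep(1, ncam), rig[seq_len(ncam)])
      sqrt(sum((sol$position - x)^2))
    }, numeric(1))
    mean(errs)
  })
  expect_true(all(diff(err_by_n) <= 0))
})

test_that("scaling the scene by k scales the triangulated point by k", {
  k <- 2.5
  rig <- fx_rig()
  rig_k <- lapply(rig, function(cm) {
    cm$translation <- cm$translation * k
    cm
  })
  x <- c(0.2, 1.1, -0.3)
  uv <- project_all(x, rig)
  uv_k <- project_all(x * k, rig_k)
  expect_equal(uv, uv_k, tolerance = 1e-9)
  sol <- triangulate_point(uv_k, rep(1, 8), rig_k)
  expect_equal(sol$position, x * k, tolerance = 1e-9)
})
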
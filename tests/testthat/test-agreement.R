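# Inter-protocol CMC, pooled Pearson, ROM error tests, Bland-Altman.

toy_waves <- function(G = 3, F_ = 101, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = F_)
  do.call(rbind, lapply(seq_len(G), function(g)
    20 * sin(2 * pi * t) + 5 * cos(4 * pi * t) + rnorm(1, 0, 0.5)))
}

test_that("CMC is exactly 1 for identical curves and degrades with offset", {
  A <- toy_waves()
  expect_identical(as.numeric(cmc_interprotocol(waveform_set(A, A))), 1)
  offs <- c(0, 2, 5, 10, 20, 40)
  cmcs <- vapply(offs, function(o)
    as.numeric(cmc_interprotocol(waveform_set(A, A + o))), numeric(1))
  finite <- cmcs[!is.nan(cmcs)]
  expect_true(all(diff(finite) <= 1e-12))
  # an offset far beyond the grand mean ROM turns the radicand negative
  expect_true(is.nan(cmcs[length(cmcs)]))
})

test_that("CMC matches brute-force evaluation of the variance ratio", {
  A <- toy_waves(G = 2, F_ = 4)
  B <- A + 0.5
  w <- waveform_set(A, B)
  Y <- w$Y; P <- 2; G <- 2; F_ <- 4
  num <- den <- 0
  for (g in seq_len(G)) {
    ygf <- colMeans(Y[, g, ]); yg <- mean(Y[, g, ])
    for (p in seq_len(P)) {
      num <- num + sum((Y[p, g, ] - ygf)^2)
      den <- den + sum((Y[p, g, ] - yg)^2)
    }
  }
  expected <- sqrt(1 - (num / (G * F_ * (P - 1))) / (den / (G * (P * F_ - 1))))
  expect_equal(as.numeric(cmc_interprotocol(w)), expected, tolerance = 1e-12)
})

test_that("CMC is invariant under a common affine rescaling", {
  A <- toy_waves(seed = 4)
  B <- A + stats::rnorm(length(A), 0, 3)
  c0 <- cmc_interprotocol(waveform_set(A, B))
  c1 <- cmc_interprotocol(waveform_set(2.7 * A - 13, 2.7 * B - 13))
  expect_equal(as.numeric(c1), as.numeric(c0), tolerance = 1e-10)
})

test_that("degenerate constant identical protocols return 1, flagged", {
  A <- matrix(5, 3, 101)
  out <- cmc_interprotocol(waveform_set(A, A))
  expect_equal(as.numeric(out), 1)
  expect_true(attr(out, "degenerate"))
})

test_that("CMC classification follows the published bands", {
  expect_equal(classify_cmc(c(0.96, 0.90, 0.80, 0.5, NaN)),
               c("excellent", "very good", "good", "poor", "none"))
  expect_equal(classify_cmc(0.95), "excellent")
  expect_equal(classify_cmc(0.85), "very good")
  expect_equal(classify_cmc(0.75), "good")
})

test_that("pooled Pearson correlation behaves as the textbook formula", {
  A <- toy_waves()
  expect_equal(pearson_pooled(waveform_set(A, A)), 1)
  expect_equal(pearson_pooled(waveform_set(A - mean(A), -(A - mean(A)))), -1)
  a <- matrix(c(1, 3, 2, 5, 4, 7, 6, 8), 2, 4)
  b <- matrix(c(2, 2, 3, 6, 3, 8, 7, 7), 2, 4)
  expect_equal(pearson_pooled(waveform_set(a, b)),
               stats::cor(as.numeric(a), as.numeric(b)))
  expect_error(pearson_pooled(waveform_set(matrix(1, 2, 4), a)),
               "zero pooled variance")
})

test_that("ROM differences and their tests are computed per cycle", {
  # ROMs A = [60, 62], B = [58, 63] -> paired diffs [2, -1], mean 0.5
  A <- rbind(c(0, 60, 10, 30), c(0, 62, 10, 30))
  B <- rbind(c(1, 59, 10, 30), c(0, 63, 10, 30))
  rt <- suppressWarnings(rom_error_test(waveform_set(A, B)))
  expect_equal(rt$diffs, c(2, -1))
  expect_equal(rt$mean, 0.5)
  expect_true(is.na(rt$ttest_p))   # G < 3: no test
  # identical protocols: all diffs zero
  rt0 <- rom_error_test(waveform_set(toy_waves(), toy_waves()))
  expect_equal(rt0$diffs, rep(0, 3))
  expect_equal(rt0$mean, 0)
})

test_that("ROM t-test type-I rate is near the 5% level under the null", {
  G <- 13
  rejections <- vapply(seq_len(400), function(r) {
    set.seed(5000 + r)
    A <- toy_waves(G = G, seed = 5000 + r)
    eps <- rnorm(G, 0, 0.02)                 # zero-mean per-cycle gain noise
    B <- t(vapply(seq_len(G), function(g)
      mean(A[g, ]) + (A[g, ] - mean(A[g, ])) * (1 + eps[g]),
      numeric(ncol(A))))
    rt <- rom_error_test(waveform_set(A, B))
    as.numeric(rt$ttest_p) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("Bland-Altman bias and limits match hand arithmetic", {
  A <- matrix(0, 1, 3)
  B <- matrix(c(2, -2, 3), 1, 3)     # d = A - B = [-2, 2, -3]
  ba <- bland_altman(waveform_set(A, B))
  expect_equal(ba$mean_err, -1)
  expect_equal(ba$sd, sqrt(7), tolerance = 1e-12)
  expect_equal(unname(ba$loa), c(-1 - 1.96 * sqrt(7), -1 + 1.96 * sqrt(7)),
               tolerance = 1e-12)
  # identical protocols: zero bias, zero-width limits
  A2 <- toy_waves()
  ba0 <- bland_altman(waveform_set(A2, A2))
  expect_equal(ba0$mean_err, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  expect_false(ba0$heteroscedastic)
})

test_that("RMSE^2 decomposes into bias^2 plus difference variance", {
  A <- toy_waves(seed = 8)
  B <- A + matrix(rnorm(length(A), 1.5, 2), nrow(A))
  ba <- bland_altman(waveform_set(A, B))
  n <- length(ba$differences)
  expect_equal(ba$rmse^2,
               ba$mean_err^2 + ba$sd^2 * (n - 1) / n, tolerance = 1e-9)
})

test_that("heteroscedasticity is detected when spread tracks magnitude", {
  set.seed(11)
  F_ <- 200
  A <- matrix(seq(1, 40, length.out = F_), 4, F_, byrow = TRUE)
  B <- A + matrix(rnorm(4 * F_, 0, 0.02), 4) * A   # error prop. to magnitude
  expect_true(bland_altman(waveform_set(A, B))$heteroscedastic)
  B2 <- A + matrix(rnorm(4 * F_, 0, 0.5), 4)
  expect_false(bland_altman(waveform_set(A, B2))$heteroscedastic)
})

test_that("the agreement table mirrors identity and offset signatures", {
  set.seed(21)
  n <- 240
  t <- seq(0, 8 - 1 / 30, by = 1 / 30)
  angles <- cbind(hip_flexion_r = 10 + 25 * sin(2 * pi * t),
                  knee_flexion_r = 30 + 20 * sin(2 * pi * t - 1))
  events <- seq(1, 240, by = 30)
  tab <- summarize_agreement(angles, angles, events, task = "walking")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$cmc, c(1, 1))
  expect_equal(tab$mean_err, c(0, 0))
  expect_equal(tab$rmse, c(0, 0))
  # a constant 15 deg hip offset: bias ~ 15, r unchanged, CMC degraded
  shifted <- angles; shifted[, "hip_flexion_r"] <- angles[, "hip_flexion_r"] + 15
  tab2 <- summarize_agreement(shifted, angles, events)
  hip <- tab2[tab2$angle == "hip_flexion_r", ]
  expect_equal(hip$mean_err, 15, tolerance = 1e-9)
  expect_equal(hip$pearson_r, 1, tolerance = 1e-9)
  expect_lt(hip$cmc, 0.9)
})

test_that("per-angle degeneracies are flagged rows, not failures", {
  angles1 <- cbind(a1 = rep(1, 100), a2 = sin(seq(0, 12, length.out = 100)))
  angles2 <- angles1
  tab <- summarize_agreement(angles1, angles2, events = c(1, 50, 100))
  expect_equal(nrow(tab), 2)
  expect_true(grepl("degenerate|zero-variance", tab$flag[tab$angle == "a1"]))
})
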
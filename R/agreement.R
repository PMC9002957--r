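# Concurrent-validation statistics for comparing two measurement systems'
# joint-angle waveforms: inter-protocol coefficient of multiple correlation
# (CMC), pooled Pearson correlation, range-of-motion error tests, and
# Bland-Altman limits of agreement.

#' Build a two-protocol waveform set
#'
#' @param protocol1,protocol2 Matrices cycles x frames of time-normalized
#'   waveforms (degrees), same dimensions.
#' @param angle,task Optional labels.
#' @return Object of class `waveform_set` (array 2 x G x F).
#' @export
waveform_set <- function(protocol1, protocol2, angle = NA_character_,
                         task = NA_character_) {
  protocol1 <- as.matrix(protocol1); protocol2 <- as.matrix(protocol2)
  if (!all(dim(protocol1) == dim(protocol2)))
    stop("both protocols must share cycle and frame counts")
  if (anyNA(protocol1) || anyNA(protocol2))
    stop("waveform sets must not contain missing samples")
  Y <- array(NA_real_, c(2, nrow(protocol1), ncol(protocol1)))
  Y[1, , ] <- protocol1
  Y[2, , ] <- protocol2
  structure(list(Y = Y, angle = angle, task = task), class = "waveform_set")
}

#' Inter-protocol coefficient of multiple correlation
#'
#' The variance-ratio CMC designed for comparing two measurement systems:
#' it is jointly sensitive to differences in correlation, gain and offset.
#' With protocols p, cycles g and normalized frames f,
#' \deqn{CMC = \sqrt{1 - \frac{\sum_{g,p,f} (Y_{pgf} - \bar Y_{gf})^2 /
#'   (G F (P - 1))}{\sum_{g,p,f} (Y_{pgf} - \bar Y_g)^2 / (G (P F - 1))}}}
#' where \eqn{\bar Y_{gf}} is the between-protocol mean at frame f of cycle
#' g and \eqn{\bar Y_g} the grand mean of cycle g. The CMC reaches 1 for
#' perfectly overlapping curves and becomes complex — reported as `NaN` —
#' when the inter-protocol offset exceeds the grand mean range of motion
#' (the radicand turns negative).
#'
#' @param w A [waveform_set()].
#' @return A number in `(-Inf, 1]`, or `NaN` for the complex case. Both
#'   protocols constant and identical return 1 (flagged degenerate via the
#'   `"degenerate"` attribute).
#' @export
cmc_interprotocol <- function(w) {
  Y <- w$Y
  P <- dim(Y)[1]; G <- dim(Y)[2]; F_ <- dim(Y)[3]
  if (F_ < 2) stop("need at least 2 normalized frames")
  y_gf <- apply(Y, c(2, 3), mean)            # between-protocol mean
  y_g <- apply(Y, 2, mean)                   # grand mean per cycle
  # explicit loops: clarity over cleverness for the defining formula
  num <- 0
  for (p in seq_len(P)) for (g in seq_len(G))
    num <- num + sum((Y[p, g, ] - y_gf[g, ])^2)
  den <- 0
  for (p in seq_len(P)) for (g in seq_len(G))
    den <- den + sum((Y[p, g, ] - y_g[g])^2)
  num <- num / (G * F_ * (P - 1))
  den <- den / (G * (P * F_ - 1))
  if (den < .Machine$double.eps) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  radicand <- 1 - num / den
  if (radicand < 0) return(NaN)
  sqrt(radicand)
}

#' Classify a CMC value
#'
#' Bands: `NaN` (complex CMC) maps to `"none"`, below 0.75 to `"poor"`,
#' 0.75-0.84 `"good"`, 0.85-0.94 `"very good"`, 0.95 and above
#' `"excellent"`.
#'
#' @param cmc Numeric CMC (possibly `NaN`).
#' @return Character classification.
#' @export
classify_cmc <- function(cmc) {
  vapply(cmc, function(x) {
    if (is.nan(x) || is.na(x)) return("none")
    if (x >= 0.95) "excellent"
    else if (x >= 0.85) "very good"
    else if (x >= 0.75) "good"
    else "poor"
  }, character(1))
}

#' Pooled Pearson correlation between protocols
#'
#' Pearson's r over all (cycle, frame) pairs pooled.
#'
#' @param w A [waveform_set()].
#' @return Correlation coefficient.
#' @export
pearson_pooled <- function(w) {
  a <- as.numeric(w$Y[1, , ]); b <- as.numeric(w$Y[2, , ])
  if (stats::sd(a) < .Machine$double.eps || stats::sd(b) < .Machine$double.eps)
    stop("undefined correlation: a protocol has zero pooled variance")
  stats::cor(a, b)
}

#' Range-of-motion (gain) error test
#'
#' Per-cycle ROM = max - min per protocol; the paired ROM differences
#' (protocol 1 minus protocol 2) quantify the gain error. Normality of the
#' differences is checked with a Shapiro-Wilk test before a paired t-test
#' of zero mean (5% significance level).
#'
#' @param w A [waveform_set()].
#' @param alpha Significance threshold (default 0.05).
#' @return List: `rom1`, `rom2`, `diffs`, `mean`, `sd`, `shapiro_p`,
#'   `ttest_p`, `significant`, `normal`.
#' @export
rom_error_test <- function(w, alpha = 0.05) {
  G <- dim(w$Y)[2]
  rom <- function(p) apply(matrix(w$Y[p, , ], nrow = G), 1,
                           function(y) max(y) - min(y))
  rom1 <- rom(1)
  rom2 <- rom(2)
  d <- rom1 - rom2
  out <- list(rom1 = rom1, rom2 = rom2, diffs = d, mean = mean(d),
              sd = if (G > 1) stats::sd(d) else NA_real_,
              shapiro_p = NA_real_, ttest_p = NA_real_,
              significant = NA, normal = NA)
  if (G < 3) {
    warning("fewer than 3 cycles: ROM tests not performed")
    return(out)
  }
  out$shapiro_p <- if (stats::sd(d) < 1e-12) 1
                   else stats::shapiro.test(d)$p.value
  out$normal <- out$shapiro_p >= alpha
  out$ttest_p <- if (stats::sd(d) < 1e-12) 1
                 else stats::t.test(rom1, rom2, paired = TRUE)$p.value
  out$significant <- out$ttest_p < alpha
  if (!out$normal)
    attr(out$ttest_p, "non_normal") <- TRUE
  out
}

#' Bland-Altman agreement analysis
#'
#' Pools the paired differences d = protocol1 - protocol2 over all cycles
#' and frames; bias = mean(d), limits of agreement = bias +/- 1.96 sd(d)
#' (the interval expected to contain 95% of differences under normality).
#' Normality of the per-cycle mean differences is checked before testing
#' the bias against zero; heteroscedasticity is declared when |d| correlates
#' significantly with the paired means.
#'
#' @param w A [waveform_set()].
#' @param alpha Significance threshold.
#' @return List: `mean_err` (bias), `sd`, `loa` (lo, hi), `bias_p`,
#'   `shapiro_p`, `heteroscedastic`, `hetero_p`, `differences`, `means`,
#'   `rmse`.
#' @export
bland_altman <- function(w, alpha = 0.05) {
  d <- as.numeric(w$Y[1, , ] - w$Y[2, , ])
  m <- as.numeric((w$Y[1, , ] + w$Y[2, , ]) / 2)
  if (length(d) < 2) stop("need at least 2 pooled points")
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(lo = bias - 1.96 * s, hi = bias + 1.96 * s)
  # per-cycle mean differences are the pairing unit for the normality check
  cyc_means <- rowMeans(matrix(w$Y[1, , ] - w$Y[2, , ],
                               nrow = dim(w$Y)[2]))
  shapiro_p <- if (length(cyc_means) >= 3 && stats::sd(cyc_means) > 1e-12)
    stats::shapiro.test(cyc_means)$p.value else NA_real_
  bias_p <- if (length(cyc_means) >= 3 && stats::sd(cyc_means) > 1e-12)
    stats::t.test(cyc_means)$p.value else NA_real_
  het <- FALSE; het_p <- NA_real_
  if (s > 1e-12 && stats::sd(m) > 1e-12) {
    ct <- stats::cor.test(abs(d), m)
    het_p <- ct$p.value
    het <- het_p < alpha
  }
  list(mean_err = bias, sd = s, loa = loa, bias_p = bias_p,
       shapiro_p = shapiro_p, heteroscedastic = het, hetero_p = het_p,
       differences = d, means = m, rmse = sqrt(mean(d^2)))
}

#' Full agreement report for paired angle waveforms
#'
#' Builds a waveform set per angle from two protocols' angle signals
#' segmented on the same events, runs the CMC, pooled Pearson correlation,
#' ROM error tests and Bland-Altman analysis, and returns one long-format
#' row per angle. Per-angle degeneracies are flagged, never fatal.
#'
#' @param angles1,angles2 Matrices frames x angles (degrees) with matching
#'   column names: the test (markerless) and reference protocols.
#' @param events Shared cycle-boundary frame indices.
#' @param normalized_length Samples per normalized cycle.
#' @param alpha Significance threshold.
#' @param task Optional task label.
#' @return data.frame with columns `task`, `angle`, `cmc`, `cmc_class`,
#'   `pearson_r`, `rom_err_mean`, `rom_err_sd`, `rom_ttest_p`, `mean_err`,
#'   `loa_lo`, `loa_hi`, `rmse`, `shapiro_rom_p`, `shapiro_bias_p`,
#'   `heteroscedastic`, `flag`.
#' @export
summarize_agreement <- function(angles1, angles2, events,
                                normalized_length = 101, alpha = 0.05,
                                task = NA_character_) {
  common <- intersect(colnames(angles1), colnames(angles2))
  rows <- lapply(common, function(a) {
    out <- data.frame(task = task, angle = a, cmc = NA_real_,
                      cmc_class = "none", pearson_r = NA_real_,
                      rom_err_mean = NA_real_, rom_err_sd = NA_real_,
                      rom_ttest_p = NA_real_, mean_err = NA_real_,
                      loa_lo = NA_real_, loa_hi = NA_real_, rmse = NA_real_,
                      shapiro_rom_p = NA_real_, shapiro_bias_p = NA_real_,
                      heteroscedastic = NA, flag = "")
    res <- try({
      c1 <- segment_and_normalize(angles1[, a], events, normalized_length)
      c2 <- segment_and_normalize(angles2[, a], events, normalized_length)
      w <- waveform_set(c1, c2, angle = a, task = task)
      cmc <- cmc_interprotocol(w)
      out$cmc <- as.numeric(cmc)
      out$cmc_class <- classify_cmc(cmc)
      if (isTRUE(attr(cmc, "degenerate"))) out$flag <- "degenerate"
      out$pearson_r <- tryCatch(pearson_pooled(w), error = function(e) {
        out$flag <<- paste(out$flag, "zero-variance"); NA_real_
      })
      rt <- suppressWarnings(rom_error_test(w, alpha))
      out$rom_err_mean <- rt$mean; out$rom_err_sd <- rt$sd
      out$rom_ttest_p <- as.numeric(rt$ttest_p)
      out$shapiro_rom_p <- rt$shapiro_p
      ba <- bland_altman(w, alpha)
      out$mean_err <- ba$mean_err
      out$loa_lo <- ba$loa[["lo"]]; out$loa_hi <- ba$loa[["hi"]]
      out$rmse <- ba$rmse
      out$shapiro_bias_p <- ba$shapiro_p
      out$heteroscedastic <- ba$heteroscedastic
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      out$flag <- paste(out$flag, "error:", attr(res, "condition")$message)
    out
  })
  do.call(rbind, rows)
}

#' Bland-Altman plot for one angle
#'
#' Differences against means, with the bias as a solid line and the limits
#' of agreement dotted. Requires ggplot2.
#'
#' @param w A [waveform_set()].
#' @param alpha Significance threshold passed to [bland_altman()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(w, alpha = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ba <- bland_altman(w, alpha)
  df <- data.frame(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$mean_err, linetype = "solid") +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dotted") +
    ggplot2::labs(x = "Mean of protocols (deg)",
                  y = "Difference (deg)",
                  title = w$angle %||% "") +
    ggplot2::theme_minimal()
}
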
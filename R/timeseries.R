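# Resampling, zero-lag low-pass filtering, coordinate-based gait event
# detection and cycle segmentation/time-normalization.

#' Band-limited resampling
#'
#' Fourier-domain resampling (spectrum truncation / zero-padding), exact for
#' band-limited content; the output length is `round(n * to_rate /
#' from_rate)`. Operates column-wise on matrices.
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @param from_rate,to_rate Sampling rates in Hz (> 0).
#' @return Resampled vector/matrix.
#' @export
resample_signal <- function(x, from_rate, to_rate) {
  if (from_rate <= 0 || to_rate <= 0) stop("rates must be positive")
  if (from_rate == to_rate) return(x)
  if (is.matrix(x))
    return(apply(x, 2, resample_signal, from_rate = from_rate,
                 to_rate = to_rate))
  n <- length(x)
  m <- round(n * to_rate / from_rate)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- keep %/% 2
  if (keep %% 2 == 1) {
    Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
    if (half > 0) Y[m - seq_len(half) + 1] <- X[n - seq_len(half) + 1]
  } else if (m >= n) {
    # upsampling with even n: split the Nyquist bin symmetrically
    Y[seq_len(half)] <- X[seq_len(half)]
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
    if (half > 1) Y[m - seq_len(half - 1) + 1] <- X[n - seq_len(half - 1) + 1]
  } else {
    # downsampling to even m: fold the two bins meeting at Nyquist
    Y[seq_len(half)] <- X[seq_len(half)]
    Y[half + 1] <- X[half + 1] + X[n - half + 1]
    if (half > 1) Y[m - seq_len(half - 1) + 1] <- X[n - seq_len(half - 1) + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Specification for a low-pass Butterworth filter
#'
#' @param order Filter order (even, >= 2); default the conventional 4.
#' @param cutoff Low-pass cutoff in Hz; default 6 Hz, the standard choice
#'   for gait kinematics (removes noise without underestimating peaks).
#' @param sample_rate Sampling rate in Hz.
#' @param zero_phase Forward-backward (zero-lag) filtering; default TRUE.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff = 6, sample_rate = 30,
                        zero_phase = TRUE) {
  if (order %% 2 != 0 || order < 2) stop("order must be even and >= 2")
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must lie in (0, sample_rate / 2)")
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

# magnitude of a digital filter at frequency f (Hz)
filter_gain <- function(bt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  bnum <- sum(bt$b * z^(seq_along(bt$b) - 1))
  aden <- sum(bt$a * z^(seq_along(bt$a) - 1))
  Mod(bnum / aden)
}

# Design the per-pass Butterworth; for dual-pass filtering the cutoff is
# corrected upward so the cascade's -3 dB point lands on the requested one.
design_butter <- function(spec) {
  target <- if (spec$zero_phase) 2^(-1 / 4) else 2^(-1 / 2)
  nyq <- spec$sample_rate / 2
  g <- function(wc) {
    bt <- signal::butter(spec$order, wc / nyq, type = "low")
    filter_gain(bt, spec$cutoff, spec$sample_rate) - target
  }
  wc <- if (spec$zero_phase)
    stats::uniroot(g, c(spec$cutoff, min(nyq * 0.999, spec$cutoff * 3)),
                   tol = 1e-10)$root
  else spec$cutoff
  signal::butter(spec$order, wc / nyq, type = "low")
}

#' Zero-lag Butterworth low-pass filtering
#'
#' Forward-backward filtering with odd reflection padding at the edges; the
#' per-pass cutoff is pre-warped so the cascade's -3 dB point sits exactly
#' at `spec$cutoff`. DC gain is exactly 1. With `zero_phase = FALSE` a
#' single causal pass at the nominal cutoff is applied.
#'
#' @param x Numeric vector or matrix (samples in rows; filtered per column).
#' @param spec A [filter_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
butterworth_lowpass <- function(x, spec = filter_spec()) {
  if (is.matrix(x))
    return(apply(x, 2, butterworth_lowpass, spec = spec))
  n <- length(x)
  if (n <= 3 * spec$order)
    stop("signal too short to filter: need more than ", 3 * spec$order,
         " samples, got ", n)
  bt <- design_butter(spec)
  pad <- min(n - 1, 3 * (spec$order + 1) * 3)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- as.numeric(signal::filter(bt, xp))
  if (spec$zero_phase) {
    y <- rev(as.numeric(signal::filter(bt, rev(y))))
  }
  y[(pad + 1):(pad + n)]
}

#' Coordinate-based gait event detection
#'
#' Heel strikes are the local maxima of the heel's position relative to the
#' sacrum along the progression axis, in the direction of travel (the
#' coordinate-based method of gait event detection); toe-offs are the
#' corresponding local minima of the toe marker. A minimum peak separation
#' of half the nominal stride time rejects double peaks from noise.
#'
#' @param heel Matrix frames x 3 (heel trajectory) or numeric vector of the
#'   progression-axis coordinate.
#' @param sacrum Matching sacrum trajectory (or vector), subtracted from the
#'   heel.
#' @param progression_axis Column index of the progression axis (default 1,
#'   world X).
#' @param direction +1 or -1 (or a per-frame vector), the sign of travel.
#' @param frame_rate Hz.
#' @param cadence Nominal cycle frequency in Hz; sets the minimum peak
#'   separation `0.5 / cadence`. NULL disables the separation constraint.
#' @param toe Optional toe trajectory for toe-off detection.
#' @return List with `heel_strikes` (frame indices) and `toe_offs`.
#' @export
detect_heel_strikes <- function(heel, sacrum, progression_axis = 1,
                                direction = 1, frame_rate = 30,
                                cadence = NULL, toe = NULL) {
  coord <- function(x) if (is.matrix(x)) x[, progression_axis] else x
  rel <- direction * (coord(heel) - coord(sacrum))
  if (stats::sd(rel) < 1e-9) {
    warning("no gait detected: relative heel position is constant")
    return(list(heel_strikes = integer(0), toe_offs = integer(0)))
  }
  min_sep <- if (is.null(cadence)) 1L
             else max(1L, floor(0.5 / cadence * frame_rate))
  # candidate peaks at a direction reversal are turning artifacts, not strikes
  flips <- if (length(direction) > 1) which(diff(direction) != 0) else integer(0)
  hs <- find_peaks(rel, min_sep, exclude = flips,
                   exclude_window = ceiling(min_sep / 3))
  to <- integer(0)
  if (!is.null(toe)) {
    rel_t <- direction * (coord(toe) - coord(sacrum))
    to <- find_peaks(-rel_t, min_sep)
  }
  list(heel_strikes = hs, toe_offs = to)
}

# local maxima with a minimum separation, highest-first greedy selection
find_peaks <- function(x, min_sep, exclude = integer(0),
                       exclude_window = 0L) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > min(x) + 1e-12]
  if (length(exclude))
    cand <- cand[vapply(cand, function(i)
      all(abs(i - exclude) > exclude_window), logical(1))]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

#' Segment a signal into time-normalized cycles
#'
#' Splits the signal at consecutive event frames and linearly time-warps
#' each cycle to `normalized_length` samples spanning 0-100% of the cycle.
#' Samples before the first and after the last event are discarded.
#'
#' @param x Numeric vector (or matrix, normalized per column into a list).
#' @param events Increasing event frame indices (cycle boundaries).
#' @param normalized_length Samples per normalized cycle (default 101,
#'   i.e. 0-100% in 1% steps).
#' @return Matrix cycles x normalized_length (vector input); list of such
#'   matrices for matrix input.
#' @export
segment_and_normalize <- function(x, events, normalized_length = 101) {
  if (is.matrix(x))
    return(lapply(stats::setNames(seq_len(ncol(x)), colnames(x)),
                  function(j) segment_and_normalize(x[, j], events,
                                                    normalized_length)))
  events <- sort(unique(as.integer(events)))
  if (length(events) < 2) {
    warning("fewer than two events: no complete cycle to normalize")
    return(matrix(numeric(0), 0, normalized_length))
  }
  out <- matrix(NA_real_, length(events) - 1, normalized_length)
  for (g in seq_len(length(events) - 1)) {
    a <- events[g]; b <- events[g + 1]
    out[g, ] <- stats::approx(seq(a, b), x[a:b],
                              xout = seq(a, b, length.out =
                                           normalized_length))$y
  }
  out
}
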
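# Synthetic gait-like motion: each DOF follows a sum of up to three
# harmonics of the task cadence, band-limited well below the 6 Hz filter
# cutoff so low-pass filtering is near-lossless on the truth. Contralateral
# limbs run half a cycle out of phase; arms swing in antiphase with the
# ipsilateral leg.

#' Motion specification for the gait simulator
#'
#' @param task One of `"walking"`, `"running"`, `"cycling"`.
#' @param cadence Cycle frequency in Hz (the metronome frequency; stride
#'   duration is its inverse).
#' @param n_cycles Number of movement cycles (>= 1).
#' @param frame_rate Sampling rate in Hz (default 30; must exceed twice the
#'   cadence).
#' @param angle_amplitudes Optional named list overriding per-DOF harmonic
#'   amplitudes (degrees; each entry a numeric vector of up to 3 harmonics).
#' @param angle_offsets Optional named numeric overriding per-DOF offsets
#'   (degrees).
#' @param stride_length Stride length in meters (walking/running; the
#'   back-and-forth excursion is capped to stay inside the camera volume).
#' @param seed Integer seed carried to downstream stochastic stages.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(task = c("walking", "running", "cycling"),
                        cadence = 1, n_cycles = 8, frame_rate = 30,
                        angle_amplitudes = NULL, angle_offsets = NULL,
                        stride_length = NULL, seed = 1L) {
  task <- match.arg(task)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (frame_rate <= 2 * cadence)
    stop("frame_rate must exceed twice the cadence")
  if (!is.null(angle_amplitudes) &&
      any(unlist(angle_amplitudes) < 0))
    stop("amplitudes must be non-negative")
  structure(list(task = task, cadence = cadence, n_cycles = n_cycles,
                 frame_rate = frame_rate,
                 angle_amplitudes = angle_amplitudes,
                 angle_offsets = angle_offsets,
                 stride_length = stride_length %||%
                   switch(task, walking = 0.65, running = 0.9, cycling = 0),
                 seed = as.integer(seed)),
            class = "motion_spec")
}

# Per-task harmonic tables: offset (deg) and harmonic amplitudes/phases.
# Rows are the right-side template; the left side is evaluated half a cycle
# later, arms swap sides.
task_waveforms <- function(task) {
  h <- function(offset, amp, phase) list(offset = offset, amp = amp,
                                         phase = phase)
  common <- list(
    pelvis_tilt = h(3, c(0, 1.5), c(0, 0)),
    pelvis_list = h(0, 2, pi / 2),
    pelvis_rotation = h(0, 6, 0),
    lumbar_flexion = h(5, c(0, 2), c(0, pi / 4)),
    hip_adduction_r = h(0, 4, pi / 2),
    hip_rotation_r = h(0, 5, 0),
    subtalar_r = h(0, 4, 0),
    shoulder_adduction_r = h(-8, 2, 0),
    elbow_flexion_r = h(25, 8, pi / 2))
  tasks <- list(
    walking = c(common, list(
      hip_flexion_r = h(8, c(25, 4), c(pi / 2, 0)),
      knee_flexion_r = h(32, c(22, 6), c(-pi / 2, pi / 3)),
      ankle_flexion_r = h(0, c(8, 4), c(pi, pi / 2)),
      shoulder_flexion_r = h(0, 12, pi / 2))),
    running = c(common, list(
      hip_flexion_r = h(18, c(30, 5), c(pi / 2, 0)),
      knee_flexion_r = h(50, c(38, 8), c(-pi / 2, pi / 3)),
      ankle_flexion_r = h(0, c(12, 6), c(pi, pi / 2)),
      shoulder_flexion_r = h(0, 18, pi / 2))),
    cycling = c(common, list(
      lumbar_flexion = h(25, 2, 0),
      hip_flexion_r = h(55, 25, pi / 2),
      knee_flexion_r = h(75, 32, -pi / 2),
      ankle_flexion_r = h(-5, 10, pi),
      shoulder_flexion_r = h(15, 2, 0),
      elbow_flexion_r = h(20, 2, 0))))
  tasks[[task]]
}

eval_harmonics <- function(hh, t, f, t_shift = 0) {
  amp <- hh$amp; phase <- hh$phase
  y <- rep(hh$offset, length(t))
  for (k in seq_along(amp))
    if (amp[k] != 0)
      y <- y + amp[k] * sin(2 * pi * k * f * (t - t_shift) + phase[k])
  y
}

#' Generate a ground-truth gait trial
#'
#' Builds periodic joint-angle trajectories (sums of up to three harmonics
#' of the cadence per DOF), runs forward kinematics to obtain 3D keypoint
#' and anatomical-marker positions, simulates back-and-forth progression by
#' reversing the pelvis translation half way, and records per-cycle events
#' (heel strikes, or crank-top proxies for cycling) and progression
#' direction. Deterministic given the spec.
#'
#' @param spec A [motion_spec()].
#' @param model A [skeletal_model()]; defaults to [default_model()].
#' @param pelvis_height Mean pelvis height in meters.
#' @return Object of class `ground_truth`: `angles` (frames x coordinates,
#'   degrees), `keypoints` (frames x keypoints x 3, meters), `seg_rot` /
#'   `seg_pos` (per-segment world poses), `event_frames`,
#'   `direction_per_cycle`, `times`, `frame_rate`, `cadence`, `task`,
#'   `model`.
#' @export
generate_motion <- function(spec, model = default_model(),
                            pelvis_height = NULL) {
  stopifnot(inherits(spec, "motion_spec"))
  f <- spec$cadence
  fs <- spec$frame_rate
  n <- round(spec$n_cycles * fs / f)
  t <- (seq_len(n) - 1) / fs
  Tcyc <- 1 / f
  wf <- task_waveforms(spec$task)
  # user overrides
  for (nm in names(spec$angle_amplitudes %||% list()))
    wf[[nm]]$amp <- spec$angle_amplitudes[[nm]]
  for (nm in names(spec$angle_offsets %||% numeric(0))) {
    if (is.null(wf[[nm]])) wf[[nm]] <- list(offset = 0, amp = 0, phase = 0)
    wf[[nm]]$offset <- spec$angle_offsets[[nm]]
  }
  unknown <- setdiff(names(wf), coordinate_names(model))
  if (length(unknown))
    stop("motion spec names unknown model DOFs: ",
         paste(unknown, collapse = ", "))
  cn <- coordinate_names(model)
  Q <- matrix(0, n, length(cn), dimnames = list(NULL, cn))
  for (nm in names(wf)) {
    base <- wf[[nm]]
    Q[, nm] <- eval_harmonics(base, t, f)
    left <- sub("_r$", "_l", nm)
    if (left != nm && left %in% cn) {
      # contralateral side: half a cycle later; arms swing with the
      # opposite leg so they get the un-shifted template
      shift <- if (grepl("^(shoulder|elbow)", nm)) 0 else Tcyc / 2
      arm_shift <- if (grepl("^(shoulder|elbow)", nm)) Tcyc / 2 else 0
      Q[, left] <- eval_harmonics(base, t, f, t_shift = shift)
      if (arm_shift > 0) Q[, nm] <- eval_harmonics(base, t, f,
                                                   t_shift = arm_shift)
    }
  }
  # pelvis translation: vertical bob, lateral sway, and capped
  # back-and-forth progression reversing half way through the pass
  ph <- pelvis_height %||% switch(spec$task, cycling = 0.85, 0.97)
  Q[, "pelvis_ty"] <- ph + 0.015 * sin(4 * pi * f * t)
  Q[, "pelvis_tz"] <- 0.012 * sin(2 * pi * f * t)
  n_fwd <- ceiling(spec$n_cycles / 2)
  stride <- spec$stride_length
  if (stride > 0) stride <- min(stride, 2.8 / n_fwd)
  dir_cycle <- rep(c(1, -1), c(n_fwd, spec$n_cycles - n_fwd))
  cyc_of_frame <- pmin(floor(t * f) + 1, spec$n_cycles)
  v <- stride * f * dir_cycle[cyc_of_frame]
  x <- cumsum(v) / fs
  x <- x - (min(x) + max(x)) / 2
  Q[, "pelvis_tx"] <- x + if (stride > 0)
    0.03 * sin(4 * pi * f * t + pi / 4) else 0
  if (spec$task == "cycling") dir_cycle[] <- 1

  # limit check against the generating model
  bounds <- coordinate_bounds(model)
  for (nm in cn) {
    if (min(Q[, nm]) < bounds$lo[nm] - 1e-9 ||
        max(Q[, nm]) > bounds$hi[nm] + 1e-9)
      stop("generated trajectory exceeds the limits of DOF ", nm)
  }

  kp_names <- model$placements$keypoint
  K <- array(NA_real_, c(n, length(kp_names), 3),
             dimnames = list(NULL, kp_names, c("x", "y", "z")))
  seg_names <- model$segments$name
  seg_rot <- lapply(stats::setNames(seg_names, seg_names),
                    function(s) array(NA_real_, c(3, 3, n)))
  seg_pos <- lapply(stats::setNames(seg_names, seg_names),
                    function(s) matrix(NA_real_, n, 3))
  for (i in seq_len(n)) {
    poses <- segment_poses(model, Q[i, ])
    for (s in seg_names) {
      seg_rot[[s]][, , i] <- poses[[s]]$R
      seg_pos[[s]][i, ] <- poses[[s]]$p
    }
    pl <- model$placements
    for (j in seq_len(nrow(pl))) {
      ps <- poses[[pl$segment[j]]]
      K[i, j, ] <- ps$p + as.numeric(ps$R %*% c(pl$lx[j], pl$ly[j], pl$lz[j]))
    }
  }

  events <- integer(spec$n_cycles)
  sacrum <- (K[, "RHip", 1] + K[, "LHip", 1]) / 2
  crit <- if (spec$task == "cycling") K[, "RAnkle", 2]
          else K[, "RHeel", 1] - sacrum
  for (c_ in seq_len(spec$n_cycles)) {
    w <- which(cyc_of_frame == c_)
    events[c_] <- w[which.max(dir_cycle[c_] * crit[w])]
  }

  structure(list(angles = Q, keypoints = K, seg_rot = seg_rot,
                 seg_pos = seg_pos, event_frames = events,
                 direction_per_cycle = dir_cycle, times = t,
                 frame_rate = fs, cadence = f, task = spec$task,
                 model = model),
            class = "ground_truth")
}
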
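# End-to-end pipeline: observations -> triangulation -> filtering -> events
# -> scaling -> inverse kinematics -> joint angles -> (optional) agreement
# against a reference channel. File-based, with a YAML configuration
# mirroring the stages' tunables, and an INFO log sufficient to replay the
# exact configuration.

#' Default pipeline configuration
#'
#' @return Nested list of stage settings; see the methods vignette for the
#'   meaning and defaults of each block.
#' @export
pipeline_config <- function() {
  list(
    paths = list(pose_dir = NULL, static_dir = NULL, rig = NULL,
                 model = NULL, reference_mot = NULL, out_dir = "out"),
    keypoints = NULL,                      # NULL: use the model's list
    triangulation = list(min_confidence = 0.3, max_reproj_error = 15,
                         weight_power = 1, max_gap = 5),
    filter = list(order = 4, cutoff = 6, zero_phase = TRUE),
    events = list(progression_axis = 1, cadence = 1, task = "walking"),
    ik = list(maxiter = 200, ftol = 1e-8, ptol = 1e-8,
              placement_offsets = NULL),
    agreement = list(normalized_length = 101, alpha = 0.05),
    seed = 1L)
}

#' Read / write a pipeline configuration (YAML)
#'
#' Unspecified fields fall back to [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @param config Configuration list.
#' @return `read_config` returns the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(pipeline_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

log_line <- function(con, ...) {
  msg <- paste0("[INFO] ", paste0(...))
  writeLines(msg, con)
  message(msg)
}

# sign of travel per frame from the sacrum progression coordinate
infer_direction <- function(x, frame_rate, cadence = 1) {
  n <- length(x)
  if (n < 15) return(rep(1, n))
  spec <- filter_spec(order = 2, cutoff = min(cadence / 2, frame_rate / 5),
                      sample_rate = frame_rate)
  xs <- butterworth_lowpass(x, spec)
  v <- c(diff(xs), 0)
  d <- sign(v)
  for (i in seq_len(n)) if (d[i] == 0) d[i] <- if (i > 1) d[i - 1] else 1
  d
}

#' Run the full markerless-kinematics pipeline
#'
#' Executes triangulate -> filter -> events -> scale (static trial) -> IK
#' -> angles -> (optional) agreement, writing a TRC of the triangulated
#' keypoints, a per-frame quality CSV, a MOT of joint angles, an RMSE CSV,
#' a cycle CSV and, when a reference MOT is configured, an agreement CSV.
#' Every stage logs its parameters and summary counts. Deterministic given
#' the configured seed.
#'
#' @param config Configuration list (see [pipeline_config()]) or a YAML
#'   path.
#' @return Invisibly, a list with the main in-memory results (`traj`,
#'   `events`, `scales`, `ik`, `angles`, `agreement`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- modifyList(pipeline_config(), config)
  p <- cfg$paths
  dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(p$out_dir, "pipeline.log"), "w")
  on.exit(close(logf))
  log_line(logf, "config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                              null = "null"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  model <- stage("model", read_model(p$model))
  rig <- stage("rig", read_rig(p$rig))
  kp_names <- cfg$keypoints %||% model$placements$keypoint
  obs <- stage("read", read_openpose_json(p$pose_dir, kp_names))
  log_line(logf, "read: ", dim(obs$u)[1], " frames, ", dim(obs$u)[2],
           " cameras, ", dim(obs$u)[3], " keypoints")

  tcfg <- cfg$triangulation
  traj <- stage("triangulate",
                triangulate_sequence(obs, rig,
                                     min_confidence = tcfg$min_confidence,
                                     max_reproj_error = tcfg$max_reproj_error,
                                     weight_power = tcfg$weight_power,
                                     max_gap = tcfg$max_gap))
  log_line(logf, "triangulate: valid ", sum(traj$valid), "/",
           length(traj$valid), ", mean cameras used ",
           round(mean(traj$n_cameras_used[traj$valid]), 2),
           ", mean residual ",
           round(mean(traj$mean_residual, na.rm = TRUE), 3), " px")
  write_trc(traj, file.path(p$out_dir, "keypoints3d.trc"),
            frame_rate = obs$frame_rate)
  utils::write.csv(
    data.frame(frame = seq_len(dim(traj$pos)[1]),
               n_cameras_min = apply(traj$n_cameras_used, 1, min),
               mean_residual = rowMeans(traj$mean_residual, na.rm = TRUE)),
    file.path(p$out_dir, "quality.csv"), row.names = FALSE)

  fspec <- filter_spec(order = cfg$filter$order, cutoff = cfg$filter$cutoff,
                       sample_rate = obs$frame_rate,
                       zero_phase = cfg$filter$zero_phase)
  ftraj <- stage("filter", {
    out <- traj
    for (k in seq_len(dim(traj$pos)[2])) {
      if (all(traj$valid[, k])) {
        out$pos[, k, ] <- butterworth_lowpass(traj$pos[, k, ], fspec)
      }
    }
    out
  })
  log_line(logf, "filter: order ", fspec$order, ", cutoff ", fspec$cutoff,
           " Hz, zero_phase ", fspec$zero_phase)

  ecfg <- cfg$events
  sacrum <- (ftraj$pos[, "RHip", ] + ftraj$pos[, "LHip", ]) / 2
  ev <- stage("events", {
    if (identical(ecfg$task, "cycling")) {
      pk <- find_peaks(ftraj$pos[, "RAnkle", 2],
                       max(1L, floor(0.5 / ecfg$cadence * obs$frame_rate)))
      list(heel_strikes = pk, toe_offs = integer(0))
    } else {
      dirv <- infer_direction(sacrum[, ecfg$progression_axis],
                              obs$frame_rate, ecfg$cadence)
      detect_heel_strikes(ftraj$pos[, "RHeel", ], sacrum,
                          progression_axis = ecfg$progression_axis,
                          direction = dirv, frame_rate = obs$frame_rate,
                          cadence = ecfg$cadence,
                          toe = ftraj$pos[, "RBigToe", ])
    }
  })
  log_line(logf, "events: ", length(ev$heel_strikes), " cycles detected")
  dirs <- if (identical(ecfg$task, "cycling")) 1 else {
    dirv <- infer_direction(sacrum[, ecfg$progression_axis],
                            obs$frame_rate, ecfg$cadence)
    dirv[ev$heel_strikes[-length(ev$heel_strikes)]]
  }
  write_cycles(ev$heel_strikes, dirs, file.path(p$out_dir, "cycles.csv"))

  scaled <- model
  scales <- NULL
  if (!is.null(p$static_dir)) {
    sres <- stage("scale", {
      sobs <- read_openpose_json(p$static_dir, kp_names)
      straj <- triangulate_sequence(sobs, rig,
                                    min_confidence = tcfg$min_confidence,
                                    max_reproj_error = tcfg$max_reproj_error,
                                    weight_power = tcfg$weight_power)
      static_kp <- apply(straj$pos, c(2, 3), stats::median)
      scale_model(model, static_kp)
    })
    scaled <- sres$model
    scales <- sres$scales
    log_line(logf, "scale: factors ",
             paste(names(scales), round(scales, 3), sep = "=",
                   collapse = ", "))
  }

  if (!is.null(cfg$ik$placement_offsets)) {
    scaled <- apply_placement_offsets(scaled, cfg$ik$placement_offsets)
    log_line(logf, "ik: applied placement offsets for ",
             paste(names(cfg$ik$placement_offsets), collapse = ", "))
  }
  ik <- stage("ik", inverse_kinematics_sequence(
    scaled, ftraj, control = list(maxiter = cfg$ik$maxiter,
                                  ftol = cfg$ik$ftol, ptol = cfg$ik$ptol)))
  log_line(logf, "ik: marker RMSE range [",
           round(min(ik$rmse, na.rm = TRUE), 4), ", ",
           round(max(ik$rmse, na.rm = TRUE), 4),
           "] m (best practice: below 0.02-0.04 m)")
  angles <- compute_joint_angles(scaled, ik)
  write_mot(ik$q, file.path(p$out_dir, "coordinates.mot"),
            frame_rate = obs$frame_rate)
  write_mot(angles, file.path(p$out_dir, "angles.mot"),
            frame_rate = obs$frame_rate)
  utils::write.csv(data.frame(frame = seq_along(ik$rmse), rmse = ik$rmse),
                   file.path(p$out_dir, "rmse.csv"), row.names = FALSE)

  agreement <- NULL
  if (!is.null(p$reference_mot)) {
    agreement <- stage("agreement", {
      ref <- read_mot(p$reference_mot)
      summarize_agreement(angles, ref$angles, ev$heel_strikes,
                          normalized_length = cfg$agreement$normalized_length,
                          alpha = cfg$agreement$alpha,
                          task = ecfg$task)
    })
    utils::write.csv(agreement, file.path(p$out_dir, "agreement.csv"),
                     row.names = FALSE)
    log_line(logf, "agreement: ", nrow(agreement), " angle rows")
  }

  invisible(list(traj = traj, filtered = ftraj, events = ev,
                 scales = scales, ik = ik, angles = angles,
                 agreement = agreement,
                 paths = list(out_dir = p$out_dir)))
}

#' Simulate a complete virtual-camera trial to disk
#'
#' Generates a ground-truth trial, observes it through a circular
#' eight-camera rig under the given corruption, and writes everything the
#' file-based pipeline needs: per-camera pose JSON for the moving trial and
#' a static (T-pose) trial, the rig and model YAML, ground-truth angles as
#' MOT, reference markers as TRC, and a ready-to-run pipeline config.
#'
#' @param out_dir Output directory.
#' @param spec A [motion_spec()].
#' @param corrupt A [corruption_spec()].
#' @param n_cameras,radius Rig layout.
#' @param soft_tissue_sd Reference-marker noise (meters).
#' @return List of paths plus the in-memory `truth`.
#' @export
simulate_trial <- function(out_dir, spec = motion_spec(),
                           corrupt = corruption_spec(),
                           n_cameras = 8, radius = 4,
                           soft_tissue_sd = 0.005) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- default_model()
  rig <- make_rig(n_cameras, radius)
  truth <- generate_motion(spec, model)
  obs <- observe_rig(truth, rig, corrupt)
  write_openpose_json(obs, file.path(out_dir, "pose"))

  static_q <- static_tpose(model)
  static_truth <- static_ground_truth(model, static_q, n_frames = 5,
                                      frame_rate = spec$frame_rate)
  static_obs <- observe_rig(static_truth, rig, corrupt)
  write_openpose_json(static_obs, file.path(out_dir, "static_pose"))

  write_rig(rig, file.path(out_dir, "rig.yaml"))
  write_model(model, file.path(out_dir, "model.yaml"))
  write_mot(truth$angles, file.path(out_dir, "truth_angles.mot"),
            frame_rate = spec$frame_rate, name = "ground_truth")
  markers <- generate_reference_markers(truth, soft_tissue_sd,
                                        seed = spec$seed + 1L)
  write_trc(markers, file.path(out_dir, "reference_markers.trc"),
            frame_rate = spec$frame_rate)
  write_cycles(truth$event_frames, truth$direction_per_cycle,
               file.path(out_dir, "truth_cycles.csv"))

  cfg <- pipeline_config()
  cfg$paths <- list(pose_dir = file.path(out_dir, "pose"),
                    static_dir = file.path(out_dir, "static_pose"),
                    rig = file.path(out_dir, "rig.yaml"),
                    model = file.path(out_dir, "model.yaml"),
                    reference_mot = file.path(out_dir, "truth_angles.mot"),
                    out_dir = file.path(out_dir, "out"))
  cfg$events$cadence <- spec$cadence
  cfg$events$task <- spec$task
  cfg$seed <- spec$seed
  write_config(cfg, file.path(out_dir, "config.yaml"))
  list(dir = out_dir, config = file.path(out_dir, "config.yaml"),
       truth = truth, obs = obs, rig = rig, model = model)
}

# T-pose used for the static scaling trial: arms abducted horizontally.
static_tpose <- function(model, pelvis_height = 0.99) {
  q <- neutral_pose(model, pelvis_height)
  q[c("shoulder_adduction_r", "shoulder_adduction_l")] <- -90
  q
}

# wrap a constant pose as a short ground-truth trial
static_ground_truth <- function(model, q, n_frames = 5, frame_rate = 30) {
  poses <- segment_poses(model, q)
  kp <- forward_kinematics(model, q)
  K <- array(rep(kp, each = n_frames),
             c(n_frames, nrow(kp), 3),
             dimnames = list(NULL, rownames(kp), c("x", "y", "z")))
  seg_names <- model$segments$name
  seg_rot <- lapply(stats::setNames(seg_names, seg_names), function(s) {
    out <- array(NA_real_, c(3, 3, n_frames))
    for (t in seq_len(n_frames)) out[, , t] <- poses[[s]]$R
    out
  })
  seg_pos <- lapply(stats::setNames(seg_names, seg_names), function(s)
    matrix(poses[[s]]$p, n_frames, 3, byrow = TRUE))
  structure(list(angles = matrix(q, n_frames, length(q), byrow = TRUE,
                                 dimnames = list(NULL, names(q))),
                 keypoints = K, seg_rot = seg_rot, seg_pos = seg_pos,
                 event_frames = integer(0), direction_per_cycle = 1,
                 times = (seq_len(n_frames) - 1) / frame_rate,
                 frame_rate = frame_rate, cadence = NA_real_,
                 task = "static", model = model),
            class = "ground_truth")
}
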
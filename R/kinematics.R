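# Forward kinematics over the segment tree. Transforms are kept as
# (R, p) pairs; composing down the tree costs one 3x3 product and one
# matrix-vector product per joint.

# internal coordinates (radians/meters) from a public vector (degrees/m)
internal_par <- function(ctx, q) {
  par <- as.numeric(q[ctx$q_names])
  ifelse(ctx$q_is_rot, deg2rad(par), par)
}

# World pose (R, p) of every segment for one coordinate vector.
segment_poses <- function(model, q) {
  ctx <- model_ctx(model)
  fk <- fk_eval(ctx, internal_par(ctx, q))
  poses <- lapply(seq_len(ctx$nseg), function(s)
    list(R = fk$Rs[[s]], p = fk$ps[s, ]))
  names(poses) <- model$segments$name
  poses
}

#' Forward kinematics: keypoint positions for one pose
#'
#' Composes parent-to-child rigid transforms down the segment tree, with
#' locked and coupled DOFs substituted automatically, and returns the world
#' positions of the model's keypoints. Joint limits are not enforced here:
#' forward kinematics answers "where would the keypoints be", including for
#' infeasible coordinate values (the inverse-kinematics solver is what clamps
#' to the constraint set).
#'
#' @param model A [skeletal_model()].
#' @param q Named coordinate vector (degrees / meters) covering
#'   [coordinate_names()].
#' @param what `"keypoints"` (default) or `"markers"`.
#' @return Numeric matrix (points x 3) with rownames, meters.
#' @export
forward_kinematics <- function(model, q, what = c("keypoints", "markers")) {
  what <- match.arg(what)
  if (!all(coordinate_names(model) %in% names(q)))
    stop("q must name every model coordinate")
  ctx <- model_ctx(model)
  fk <- fk_eval(ctx, internal_par(ctx, q), markers = (what == "markers"))
  if (what == "keypoints") fk$kp else fk$mk
}

#' Measurement-based scaling of a skeletal model
#'
#' Sizes the generic model to a subject from a single static frame of 3D
#' keypoints: each segment's scale factor is the ratio of the experimental
#' to the model distance for its configured keypoint pair(s), averaged when
#' several pairs map to one segment. Segments without a configured pair
#' inherit their parent's factor (1 at the root). Scaling multiplies the
#' segment's own keypoint/marker placements and the joint locations of its
#' child segments.
#'
#' @param model A [skeletal_model()].
#' @param static_keypoints Matrix (keypoints x 3) of one static frame,
#'   meters, rownames = keypoint names.
#' @return List with `model` (scaled) and `scales` (named numeric factors).
#' @export
scale_model <- function(model, static_keypoints) {
  q0 <- neutral_pose(model)
  ref <- forward_kinematics(model, q0)
  scales <- stats::setNames(rep(NA_real_, nrow(model$segments)),
                            model$segments$name)
  for (segname in names(model$measurement_pairs)) {
    ratios <- vapply(model$measurement_pairs[[segname]], function(pair) {
      if (!all(pair %in% rownames(static_keypoints)))
        stop("scaling pair ", paste(pair, collapse = "-"),
             " missing from the static frame")
      d_exp <- sqrt(sum((static_keypoints[pair[1], ] -
                         static_keypoints[pair[2], ])^2))
      d_mod <- sqrt(sum((ref[pair[1], ] - ref[pair[2], ])^2))
      if (d_exp <= 0 || d_mod <= 0)
        stop("non-positive distance for scaling pair ",
             paste(pair, collapse = "-"))
      d_exp / d_mod
    }, numeric(1))
    scales[segname] <- mean(ratios)
  }
  # inherit down the tree
  for (s in model$topo) {
    if (is.na(scales[s])) {
      par <- model$segments$parent[match(s, model$segments$name)]
      scales[s] <- if (is.na(par)) 1 else scales[par]
    }
  }
  scaled <- model
  for (i in seq_len(nrow(scaled$segments))) {
    par <- scaled$segments$parent[i]
    if (!is.na(par)) {
      f <- scales[par]   # child joint location lives in the parent's frame
      scaled$segments$ox[i] <- scaled$segments$ox[i] * f
      scaled$segments$oy[i] <- scaled$segments$oy[i] * f
      scaled$segments$oz[i] <- scaled$segments$oz[i] * f
    }
  }
  f_kp <- scales[scaled$placements$segment]
  scaled$placements$lx <- scaled$placements$lx * f_kp
  scaled$placements$ly <- scaled$placements$ly * f_kp
  scaled$placements$lz <- scaled$placements$lz * f_kp
  if (nrow(scaled$markers)) {
    f_mk <- scales[scaled$markers$segment]
    scaled$markers$lx <- scaled$markers$lx * f_mk
    scaled$markers$ly <- scaled$markers$ly * f_mk
    scaled$markers$lz <- scaled$markers$lz * f_mk
  }
  # rebuild so the compiled kinematics cache reflects the new geometry
  scaled <- skeletal_model(scaled$segments, scaled$dofs, scaled$placements,
                           scaled$markers, scaled$couplings,
                           scaled$measurement_pairs)
  list(model = scaled, scales = scales)
}

#' Default keypoint weights for scaling and inverse kinematics
#'
#' All keypoints weighted 1, except Nose and Head (0.1) and the shoulder and
#' hip keypoints (2); face points are noisy and poorly localized while the
#' proximal torso keypoints anchor the pose.
#'
#' @param model A [skeletal_model()].
#' @return Named numeric weight vector.
#' @export
default_keypoint_weights <- function(model) {
  kp <- model$placements$keypoint
  w <- stats::setNames(rep(1, length(kp)), kp)
  w[kp %in% c("Nose", "Head")] <- 0.1
  w[kp %in% c("RShoulder", "LShoulder", "RHip", "LHip")] <- 2
  w
}

#' Default zero-angle prior weights for the static (scaling) pose
#'
#' Weight 1 on a zero angle for pelvis list, pelvis tilt, lumbar (L5-S1)
#' flexion, and the ankle angles: a subject standing upright with flat feet
#' is assumed during the static trial. These priors apply only to static
#' solves; dynamic frames use keypoint terms alone.
#'
#' @return Named numeric weight vector (per DOF).
#' @export
default_pose_priors <- function() {
  c(pelvis_list = 1, pelvis_tilt = 1, lumbar_flexion = 1,
    ankle_flexion_r = 1, ankle_flexion_l = 1,
    subtalar_r = 1, subtalar_l = 1)
}
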
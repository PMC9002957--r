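# Corruption model for synthetic 2D observations: constant per-keypoint 3D
# offsets (emulating the systematic joint-center bias of deep-learning pose
# estimators, up to a few centimeters), Gaussian pixel noise, and per-camera
# occlusion dropouts with a confidence model tied to the injected error.

#' Corruption specification for synthetic observations
#'
#' @param pixel_noise_sd Gaussian pixel noise standard deviation (pixels).
#' @param systematic_offsets Named list of per-keypoint 3-vectors (meters);
#'   each keypoint's offset is constant over time. Magnitudes are bounded at
#'   0.1 m.
#' @param offset_frame `"segment"` (default; offsets travel with the limb,
#'   emulating anatomical mislabeling) or `"world"` (fixed shift).
#' @param occlusions data.frame with columns `camera`, `keypoint`, `from`,
#'   `to` (frame intervals dropped per camera, confidence forced to 0).
#' @param confidence_scale Pixel error that drives confidence to 0; visible
#'   keypoints get `clamp(1 - pixel_error / confidence_scale, 0, 1)`.
#' @param seed Integer RNG seed; observations are deterministic given it.
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(pixel_noise_sd = 0, systematic_offsets = list(),
                            offset_frame = c("segment", "world"),
                            occlusions = NULL, confidence_scale = 20,
                            seed = 1L) {
  offset_frame <- match.arg(offset_frame)
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  for (nm in names(systematic_offsets)) {
    v <- systematic_offsets[[nm]]
    if (length(v) != 3 || sqrt(sum(v^2)) > 0.1)
      stop("systematic offset for ", nm,
           " must be a 3-vector of magnitude <= 0.1 m")
  }
  if (is.null(occlusions))
    occlusions <- data.frame(camera = integer(), keypoint = character(),
                             from = integer(), to = integer())
  structure(list(pixel_noise_sd = pixel_noise_sd,
                 systematic_offsets = systematic_offsets,
                 offset_frame = offset_frame, occlusions = occlusions,
                 confidence_scale = confidence_scale,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Observe a ground-truth trial through a camera rig
#'
#' Each keypoint is first displaced by its constant systematic 3D offset
#' (in the owning segment's frame by default, so the bias travels with the
#' limb), then projected through every camera, then perturbed by Gaussian
#' pixel noise. Occluded or out-of-view entries carry confidence 0; visible
#' entries get a confidence that decays linearly with the injected pixel
#' error. Deterministic given the corruption seed.
#'
#' @param truth A `ground_truth` from [generate_motion()].
#' @param rig List of [camera_params()].
#' @param corrupt A [corruption_spec()].
#' @return Object of class `keypoint_observations`: arrays `u`, `v`, `conf`
#'   (frames x cameras x keypoints), `keypoints`, `cameras`, `frame_rate`.
#' @export
observe_rig <- function(truth, rig, corrupt = corruption_spec()) {
  if (!length(rig)) stop("rig must contain at least one camera")
  K <- truth$keypoints
  n <- dim(K)[1]; n_k <- dim(K)[2]; n_c <- length(rig)
  kp <- dimnames(K)[[2]]
  # apply systematic offsets
  if (length(corrupt$systematic_offsets)) {
    pl <- truth$model$placements
    for (nm in names(corrupt$systematic_offsets)) {
      j <- match(nm, kp)
      if (is.na(j)) next
      off <- corrupt$systematic_offsets[[nm]]
      if (corrupt$offset_frame == "world") {
        K[, j, ] <- K[, j, ] + rep(off, each = n)
      } else {
        seg <- pl$segment[match(nm, pl$keypoint)]
        Rs <- truth$seg_rot[[seg]]
        for (t in seq_len(n))
          K[t, j, ] <- K[t, j, ] + as.numeric(Rs[, , t] %*% off)
      }
    }
  }
  u <- v <- array(NA_real_, c(n, n_c, n_k),
                  dimnames = list(NULL, NULL, kp))
  conf <- array(0, c(n, n_c, n_k), dimnames = list(NULL, NULL, kp))
  noise <- with_seed(corrupt$seed,
                     array(stats::rnorm(2 * n * n_c * n_k, 0,
                                        max(corrupt$pixel_noise_sd, 0)),
                           c(n, n_c, n_k, 2)))
  if (corrupt$pixel_noise_sd == 0) noise[] <- 0
  Xw <- matrix(K, n * n_k, 3)   # (frame, keypoint) rows, column-major
  for (c_ in seq_len(n_c)) {
    cam <- rig[[c_]]
    pc <- Xw %*% t(cam$rotation) +
      matrix(cam$translation, n * n_k, 3, byrow = TRUE)
    z <- pc[, 3]
    uu <- cam$focal[1] * pc[, 1] / z + cam$center[1]
    vv <- cam$focal[2] * pc[, 2] / z + cam$center[2]
    vis <- z > 1e-12 & uu >= 0 & uu <= cam$image_size[1] &
      vv >= 0 & vv <= cam$image_size[2]
    e1 <- matrix(noise[, c_, , 1], n * n_k)
    e2 <- matrix(noise[, c_, , 2], n * n_k)
    cf <- pmin(pmax(1 - sqrt(e1^2 + e2^2) / corrupt$confidence_scale, 0), 1)
    uu <- uu + e1; vv <- vv + e2
    uu[!vis] <- NA_real_; vv[!vis] <- NA_real_; cf[!vis] <- 0
    u[, c_, ] <- uu
    v[, c_, ] <- vv
    conf[, c_, ] <- cf
  }
  if (nrow(corrupt$occlusions)) {
    for (i in seq_len(nrow(corrupt$occlusions))) {
      oc <- corrupt$occlusions[i, ]
      kk <- if (oc$keypoint == "*") seq_len(n_k) else match(oc$keypoint, kp)
      fr <- max(1, oc$from):min(n, oc$to)
      conf[fr, oc$camera, kk] <- 0
    }
  }
  structure(list(u = u, v = v, conf = conf, keypoints = kp,
                 cameras = vapply(rig, function(cm) cm$name %||% "cam",
                                  character(1)),
                 frame_rate = truth$frame_rate),
            class = "keypoint_observations")
}

#' Generate marker-based reference trajectories
#'
#' Emits the anatomical/cluster marker channel of a ground-truth trial:
#' marker positions follow their segments rigidly (landmark midpoints thus
#' coincide with the true joint centers), with independent Gaussian noise
#' of `soft_tissue_sd` added per axis to mimic soft-tissue and labeling
#' error.
#'
#' @param truth A `ground_truth`.
#' @param soft_tissue_sd Noise standard deviation in meters.
#' @param seed RNG seed (defaults to a fixed value for reproducibility).
#' @return Object of class `marker_set`: `pos` (frames x markers x 3),
#'   `markers` (the model marker table), `frame_rate`.
#' @export
generate_reference_markers <- function(truth, soft_tissue_sd = 0.005,
                                       seed = 2L) {
  mk <- truth$model$markers
  if (!nrow(mk)) stop("model defines no reference markers")
  joints <- stats::na.omit(unique(mk$joint))
  for (j in joints) {
    rows <- mk[!is.na(mk$joint) & mk$joint == j, ]
    if (nrow(rows) == 0)
      stop("missing landmark pair for joint ", j)
  }
  n <- dim(truth$keypoints)[1]
  m <- nrow(mk)
  pos <- array(NA_real_, c(n, m, 3), dimnames = list(NULL, mk$name,
                                                     c("x", "y", "z")))
  for (i in seq_len(m)) {
    Rs <- truth$seg_rot[[mk$segment[i]]]
    ps <- truth$seg_pos[[mk$segment[i]]]
    loc <- c(mk$lx[i], mk$ly[i], mk$lz[i])
    for (t in seq_len(n))
      pos[t, i, ] <- ps[t, ] + as.numeric(Rs[, , t] %*% loc)
  }
  if (soft_tissue_sd > 0)
    pos <- pos + with_seed(seed,
                           array(stats::rnorm(length(pos), 0, soft_tissue_sd),
                                 dim(pos)))
  structure(list(pos = pos, markers = mk, frame_rate = truth$frame_rate),
            class = "marker_set")
}

#' Joint centers from a marker set
#'
#' Computes the marker-based joint centers: midpoints of medial/lateral
#' landmark pairs for ankles, knees, elbows, wrists and shoulders (single
#' markers pass through), and functional hip centers from the thigh marker
#' clusters, sphere-fit in a pelvis frame built from the four pelvis
#' landmarks.
#'
#' @param markers A `marker_set` from [generate_reference_markers()].
#' @param functional_hip Use the sphere-fit functional method for the hips
#'   (default TRUE; requires thigh clusters and pelvis landmarks).
#' @return Array frames x joints x 3 whose joint names match the model's
#'   keypoint names, usable directly as inverse-kinematics targets.
#' @export
marker_joint_centers <- function(markers, functional_hip = TRUE) {
  mk <- markers$markers
  pos <- markers$pos
  n <- dim(pos)[1]
  joints <- stats::na.omit(unique(mk$joint))
  out_names <- c(joints, if (functional_hip) c("RHip", "LHip"))
  out <- array(NA_real_, c(n, length(out_names), 3),
               dimnames = list(NULL, out_names, c("x", "y", "z")))
  for (j in joints) {
    rows <- which(!is.na(mk$joint) & mk$joint == j)
    out[, j, ] <- if (length(rows) == 1) pos[, rows, ]
                  else apply(pos[, rows, , drop = FALSE], c(1, 3), mean)
  }
  if (functional_hip) {
    pf <- pelvis_frame_from_markers(pos)
    for (side in c("R", "L")) {
      cl <- which(mk$type == "cluster" & startsWith(mk$name, side))
      if (length(cl) < 1) stop("no thigh cluster markers for side ", side)
      fit <- functional_joint_center(pos[, cl, , drop = FALSE],
                                     ref_rotation = pf$R,
                                     ref_position = pf$p)
      for (t in seq_len(n))
        out[t, paste0(side, "Hip"), ] <-
          pf$p[t, ] + as.numeric(pf$R[, , t] %*% fit$center)
    }
  }
  out
}

# Technical pelvis frame from the four pelvis landmarks (anterior and
# posterior iliac spine markers).
pelvis_frame_from_markers <- function(pos) {
  need <- c("RASI", "LASI", "RPSI", "LPSI")
  if (!all(need %in% dimnames(pos)[[2]]))
    stop("pelvis landmarks RASI/LASI/RPSI/LPSI are required")
  n <- dim(pos)[1]
  R <- array(NA_real_, c(3, 3, n))
  p <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    rasi <- pos[t, "RASI", ]; lasi <- pos[t, "LASI", ]
    rpsi <- pos[t, "RPSI", ]; lpsi <- pos[t, "LPSI", ]
    origin <- (rasi + lasi) / 2
    z <- normalize3(rasi - lasi)
    x0 <- origin - (rpsi + lpsi) / 2
    x <- normalize3(x0 - sum(x0 * z) * z)
    y <- cross3(z, x)
    R[, , t] <- cbind(x, y, z)
    p[t, ] <- origin
  }
  list(R = R, p = p)
}

#' Marker weights preset for the reference (marker-based) channel
#'
#' Joint-center targets weighted 5, cluster markers 1, other anatomical
#' markers 2 — the conventional weighting for marker-based scaling and
#' inverse kinematics.
#'
#' @param marker_table A marker table (`markers` element of a `marker_set`).
#' @return Named numeric weights.
#' @export
reference_marker_weights <- function(marker_table) {
  w <- ifelse(!is.na(marker_table$joint), 5,
              ifelse(marker_table$type == "cluster", 1, 2))
  stats::setNames(w, marker_table$name)
}
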
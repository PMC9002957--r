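# Confidence-weighted, robust multi-view triangulation (Direct Linear
# Transform). Each camera contributes two linear rows; "weighted" multiplies
# a camera's rows by its keypoint confidence so unreliable detections pull
# less on the solution.

#' Triangulate one point from weighted 2D observations
#'
#' Solves the homogeneous DLT system whose per-camera rows are scaled by
#' that camera's confidence (linear weighting by default; squared
#' selectable). The solution is the right singular vector of the smallest
#' singular value, dehomogenized. Observations below `min_confidence` are
#' dropped; fewer than two usable observations yields an invalid result,
#' not an error.
#'
#' @param uv Matrix (cameras x 2) of pixel coordinates (NA = missing).
#' @param conf Numeric confidences in `[0, 1]` per camera.
#' @param rig List of [camera_params()] matching the rows of `uv`.
#' @param min_confidence Minimum confidence to admit an observation.
#' @param weight_power 1 (linear, default) or 2 (squared confidence).
#' @return List with `position` (3-vector or NA), `residuals` (pixel
#'   reprojection distance per input camera, NA where unused), `used`
#'   (logical per camera), `valid`.
#' @export
triangulate_point <- function(uv, conf, rig, min_confidence = 0.3,
                              weight_power = 1) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  usable <- which(conf >= min_confidence & !is.na(uv[, 1]) & !is.na(uv[, 2]) &
                  conf > 0)
  res <- rep(NA_real_, nrow(uv))
  if (length(usable) < 2)
    return(list(position = rep(NA_real_, 3), residuals = res,
                used = rep(FALSE, nrow(uv)), valid = FALSE))
  A <- matrix(0, 2 * length(usable), 4)
  for (k in seq_along(usable)) {
    i <- usable[k]
    P <- projection_matrix(rig[[i]])
    w <- conf[i]^weight_power
    A[2 * k - 1, ] <- w * (uv[i, 1] * P[3, ] - P[1, ])
    A[2 * k, ]     <- w * (uv[i, 2] * P[3, ] - P[2, ])
  }
  v <- svd(A, nu = 0)$v[, 4]
  if (abs(v[4]) < 1e-14)
    return(list(position = rep(NA_real_, 3), residuals = res,
                used = rep(FALSE, nrow(uv)), valid = FALSE))
  x <- v[1:3] / v[4]
  for (i in usable) {
    p <- project_point(x, rig[[i]])
    res[i] <- sqrt(sum((p - uv[i, ])^2))
  }
  used <- rep(FALSE, nrow(uv)); used[usable] <- TRUE
  list(position = x, residuals = res, used = used, valid = TRUE)
}

#' Robust triangulation with iterative camera exclusion
#'
#' Triangulates, then, while the mean reprojection residual exceeds
#' `max_reproj_error` and more than two cameras remain, removes the camera
#' with the largest residual and re-solves. Ties are broken toward dropping
#' the lower-confidence camera, then the lower camera index. If even the
#' final two-camera solution violates the threshold it is returned flagged
#' low quality.
#'
#' @inheritParams triangulate_point
#' @param max_reproj_error Mean reprojection residual to accept, pixels.
#' @return As [triangulate_point()], plus `low_quality` and
#'   `n_cameras_used`, `mean_residual`.
#' @export
robust_triangulate <- function(uv, conf, rig, max_reproj_error = 15,
                               min_confidence = 0.3, weight_power = 1) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  active <- conf >= min_confidence & conf > 0 & !is.na(uv[, 1])
  repeat {
    conf_a <- ifelse(active, conf, 0)
    sol <- triangulate_point(uv, conf_a, rig,
                             min_confidence = min_confidence,
                             weight_power = weight_power)
    if (!sol$valid)
      return(c(sol, list(low_quality = TRUE, n_cameras_used = 0L,
                         mean_residual = NA_real_)))
    mres <- mean(sol$residuals[sol$used])
    n_used <- sum(sol$used)
    if (mres <= max_reproj_error || n_used <= 2) {
      return(c(sol, list(low_quality = mres > max_reproj_error,
                         n_cameras_used = as.integer(n_used),
                         mean_residual = mres)))
    }
    worst <- max(sol$residuals[sol$used])
    cand <- which(sol$used & sol$residuals >= worst - 1e-12)
    if (length(cand) > 1) {
      cand <- cand[order(conf[cand], cand)]   # lower confidence, lower index
    }
    active[cand[1]] <- FALSE
  }
}

#' Triangulate an observation set into 3D trajectories
#'
#' Applies [robust_triangulate()] independently per frame and keypoint,
#' then linearly interpolates interior invalid runs of up to `max_gap`
#' frames; longer gaps (and leading/trailing gaps) remain invalid.
#'
#' @param obs A `keypoint_observations` object (see [observe_rig()] /
#'   [read_openpose_json()]).
#' @param rig List of [camera_params()] matching the observation cameras.
#' @param min_confidence,max_reproj_error,weight_power Triangulation
#'   settings.
#' @param max_gap Longest interior gap (frames) to fill by interpolation.
#' @return Object of class `trajectory3d`: `pos` (frames x keypoints x 3),
#'   `n_cameras_used`, `mean_residual`, `valid`, `interpolated` (all
#'   frames x keypoints), `keypoints`, `frame_rate`.
#' @export
triangulate_sequence <- function(obs, rig, min_confidence = 0.3,
                                 max_reproj_error = 15, weight_power = 1,
                                 max_gap = 5) {
  n_f <- dim(obs$u)[1]; n_c <- dim(obs$u)[2]; n_k <- dim(obs$u)[3]
  if (n_c != length(rig))
    stop("rig size (", length(rig), ") does not match observation cameras (",
         n_c, ")")
  kp <- obs$keypoints
  pos <- array(NA_real_, c(n_f, n_k, 3), dimnames = list(NULL, kp, c("x", "y", "z")))
  ncams <- matrix(0L, n_f, n_k, dimnames = list(NULL, kp))
  mres <- matrix(NA_real_, n_f, n_k, dimnames = list(NULL, kp))
  valid <- matrix(FALSE, n_f, n_k, dimnames = list(NULL, kp))
  interp <- matrix(FALSE, n_f, n_k, dimnames = list(NULL, kp))
  for (t in seq_len(n_f)) {
    for (k in seq_len(n_k)) {
      sol <- robust_triangulate(cbind(obs$u[t, , k], obs$v[t, , k]),
                                obs$conf[t, , k], rig,
                                max_reproj_error = max_reproj_error,
                                min_confidence = min_confidence,
                                weight_power = weight_power)
      if (sol$valid) {
        pos[t, k, ] <- sol$position
        ncams[t, k] <- sol$n_cameras_used
        mres[t, k] <- sol$mean_residual
        valid[t, k] <- TRUE
      }
    }
  }
  # interior gap filling
  for (k in seq_len(n_k)) {
    ok <- which(valid[, k])
    if (length(ok) < 2) next
    gaps <- rle(!valid[, k])
    idx <- cumsum(c(1, gaps$lengths))
    for (g in seq_along(gaps$lengths)) {
      if (!gaps$values[g]) next
      a <- idx[g]; b <- idx[g + 1] - 1
      if (a == 1 || b == n_f || (b - a + 1) > max_gap) next
      for (d in 1:3) {
        pos[a:b, k, d] <- stats::approx(c(a - 1, b + 1),
                                        pos[c(a - 1, b + 1), k, d],
                                        xout = a:b)$y
      }
      valid[a:b, k] <- TRUE
      interp[a:b, k] <- TRUE
    }
  }
  structure(list(pos = pos, n_cameras_used = ncams, mean_residual = mres,
                 valid = valid, interpolated = interp, keypoints = kp,
                 frame_rate = obs$frame_rate),
            class = "trajectory3d")
}
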
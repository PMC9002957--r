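# Systematic-offset compensation: deep-learning pose estimators mislocate
# joint centers by a constant amount in the limb's own frame. The remedy is
# the overlay procedure: estimate each keypoint's average offset in its
# segment frame from a solved trial, then shift the model's keypoint
# placements so the model expects the biased locations.

#' Estimate per-keypoint placement offsets from a solved trial
#'
#' For every keypoint, averages the residual between the experimental
#' (triangulated) position and the model keypoint position over all frames,
#' expressed in the owning segment's frame of the inverse-kinematics
#' solution. A constant segment-frame bias (anatomical mislabeling) shows
#' up as a stable mean; random noise averages out.
#'
#' @param model The (scaled) model used for the solve.
#' @param traj A `trajectory3d` or frames x keypoints x 3 array.
#' @param ik The `ik_result` for `traj`.
#' @param keypoints Keypoints to estimate (default: all).
#' @return Named list of 3-vectors (meters, segment frame).
#' @export
estimate_placement_offsets <- function(model, traj, ik,
                                       keypoints = NULL) {
  arr <- trajectory_array(traj)
  ctx <- model_ctx(model)
  kp <- keypoints %||% ctx$kp_names
  n <- dim(arr)[1]
  acc <- matrix(0, length(kp), 3, dimnames = list(kp, NULL))
  cnt <- numeric(length(kp))
  for (t in seq_len(n)) {
    fk <- fk_eval(ctx, internal_par(ctx, ik$q[t, ]))
    for (i in seq_along(kp)) {
      k <- match(kp[i], ctx$kp_names)
      x <- arr[t, kp[i], ]
      if (anyNA(x)) next
      s <- ctx$kp_seg[k]
      acc[i, ] <- acc[i, ] + as.numeric(crossprod(fk$Rs[[s]],
                                                  x - fk$kp[k, ]))
      cnt[i] <- cnt[i] + 1
    }
  }
  out <- lapply(seq_along(kp), function(i)
    if (cnt[i] > 0) acc[i, ] / cnt[i] else c(0, 0, 0))
  stats::setNames(out, kp)
}

#' Shift model keypoint placements by per-keypoint offsets
#'
#' Applies config-supplied (or [estimate_placement_offsets()]-measured)
#' segment-frame offsets to the model's keypoint placements, so inverse
#' kinematics expects the biased keypoint locations instead of the true
#' joint centers. Defaults to no change for unnamed keypoints.
#'
#' @param model A [skeletal_model()].
#' @param offsets Named list of 3-vectors (meters, segment frame).
#' @return The adjusted model.
#' @export
apply_placement_offsets <- function(model, offsets) {
  pl <- model$placements
  for (nm in names(offsets)) {
    i <- match(nm, pl$keypoint)
    if (is.na(i)) next
    pl$lx[i] <- pl$lx[i] + offsets[[nm]][1]
    pl$ly[i] <- pl$ly[i] + offsets[[nm]][2]
    pl$lz[i] <- pl$lz[i] + offsets[[nm]][3]
  }
  skeletal_model(model$segments, model$dofs, pl, model$markers,
                 model$couplings, model$measurement_pairs)
}
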
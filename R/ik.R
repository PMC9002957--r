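# Constrained inverse kinematics: per-frame bounded nonlinear least squares
# keeping model keypoints close to experimental keypoints, with joint locks,
# limits and couplings enforced by construction (locked/coupled DOFs are not
# coordinates; limits are optimizer bounds).

ik_control_default <- function() {
  list(maxiter = 200, ftol = 1e-8, ptol = 1e-8)
}

#' Solve inverse kinematics for one frame
#'
#' Minimizes the weighted sum of squared distances between experimental and
#' model keypoints, optionally with zero-angle priors (used for static
#' scaling poses), subject to the model's locks, limits and couplings.
#' Invalid keypoints (NA coordinates or zero weight) are excluded from the
#' objective.
#'
#' @param model A (scaled) [skeletal_model()].
#' @param keypoints Matrix (keypoints x 3), meters, rownames = keypoint
#'   names; NA rows are treated as invalid.
#' @param weights Named keypoint weights; defaults to
#'   [default_keypoint_weights()].
#' @param q_init Named starting coordinates (degrees / meters); defaults to
#'   [neutral_pose()].
#' @param priors Named zero-angle prior weights per DOF, or NULL for none.
#' @param control List of solver settings (`maxiter`, `ftol`, `ptol`).
#' @return List with `q` (named coordinates, degrees / meters), `rmse`
#'   (weighted marker RMSE, meters), `n_keypoints`, `converged`,
#'   `objective_trace` (non-increasing residual sum of squares), `valid`.
#' @export
inverse_kinematics_frame <- function(model, keypoints,
                                     weights = default_keypoint_weights(model),
                                     q_init = neutral_pose(model),
                                     priors = NULL,
                                     control = ik_control_default(),
                                     ctx = model_ctx(model)) {
  vi <- match(rownames(keypoints), ctx$kp_names)
  ok <- !is.na(vi) & stats::complete.cases(keypoints) &
    (weights[rownames(keypoints)] %||% 1) > 0
  vi <- vi[ok]
  if (length(vi) < 3) {
    return(list(q = q_init, rmse = NA_real_, n_keypoints = length(vi),
                converged = FALSE, objective_trace = numeric(0),
                valid = FALSE))
  }
  target <- keypoints[ok, , drop = FALSE]
  wts <- weights[ctx$kp_names[vi]]
  w <- sqrt(wts)
  to_public <- function(p) stats::setNames(
    ifelse(ctx$q_is_rot, rad2deg(p), p), ctx$q_names)
  prior_idx <- match(intersect(names(priors %||% numeric(0)), ctx$q_names),
                     ctx$q_names)
  pw <- if (length(prior_idx))
    sqrt(priors[ctx$q_names[prior_idx]]) else numeric(0)
  p0 <- pmin(pmax(internal_par(ctx, q_init), ctx$lower), ctx$upper)
  # Levenberg-Marquardt needs >= as many residuals as parameters; with very
  # few keypoints, add a vanishing ridge toward the warm start
  n_data <- 3 * length(vi) + length(prior_idx)
  ridge <- if (n_data < ctx$nq) 1e-6 else 0
  resid_fn <- function(par) {
    kp <- fk_eval(ctx, par)$kp[vi, , drop = FALSE]
    r <- as.numeric(w * (kp - target))
    if (length(prior_idx)) r <- c(r, pw * par[prior_idx])
    if (ridge > 0) r <- c(r, ridge * (par - p0))
    r
  }
  jac_fn <- function(par) {
    fk <- fk_eval(ctx, par, jacobian = TRUE)
    n_row <- n_data + if (ridge > 0) ctx$nq else 0L
    J <- matrix(0, n_row, ctx$nq)
    for (qi in seq_len(ctx$nq))
      J[seq_len(3 * length(vi)), qi] <-
        as.numeric(w * fk$J[vi, , qi, drop = FALSE])
    for (k in seq_along(prior_idx))
      J[3 * length(vi) + k, prior_idx[k]] <- pw[k]
    if (ridge > 0)
      J[n_data + seq_len(ctx$nq), ] <- diag(ridge, ctx$nq)
    J
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = ctx$lower, upper = ctx$upper, fn = resid_fn,
    jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = control$maxiter, ftol = control$ftol, ptol = control$ptol))
  q_hat <- to_public(fit$par)
  pos <- fk_eval(ctx, fit$par)$kp[vi, , drop = FALSE]
  d2 <- rowSums((pos - target)^2)
  rmse <- sqrt(sum(wts * d2) / sum(wts))
  list(q = q_hat, rmse = rmse, n_keypoints = length(vi),
       converged = fit$info %in% 1:4, objective_trace = fit$rsstrace,
       valid = TRUE)
}

#' Solve inverse kinematics over a trajectory
#'
#' Frame 0 starts from the neutral pose; each subsequent frame is
#' warm-started from the previous solution, which keeps the solver fast and
#' the recovered coordinates continuous on band-limited motion. Reports the
#' per-frame weighted marker RMSE so runs can be screened against the
#' 2-4 cm best-practice bound for marker fit.
#'
#' @param model A (scaled) [skeletal_model()].
#' @param traj A `trajectory3d` (see [triangulate_sequence()]) or a numeric
#'   array frames x keypoints x 3 with keypoint dimnames.
#' @param weights Named keypoint weights.
#' @param q_init Starting coordinates for the first frame.
#' @param control Solver settings.
#' @return List of class `ik_result`: `q` (frames x coordinates matrix,
#'   degrees / meters), `rmse` (per frame, meters), `converged`, `valid`.
#' @export
inverse_kinematics_sequence <- function(model, traj,
                                        weights = default_keypoint_weights(model),
                                        q_init = neutral_pose(model),
                                        control = ik_control_default()) {
  arr <- trajectory_array(traj)
  n <- dim(arr)[1]
  if (n == 0) stop("empty trajectory")
  cn <- coordinate_names(model)
  Q <- matrix(NA_real_, n, length(cn), dimnames = list(NULL, cn))
  rmse <- rep(NA_real_, n)
  converged <- valid <- logical(n)
  q_prev <- q_init
  ctx <- model_ctx(model)
  for (i in seq_len(n)) {
    kp <- arr[i, , , drop = TRUE]
    if (is.null(dim(kp))) kp <- matrix(kp, ncol = 3,
                                       dimnames = list(dimnames(arr)[[2]], NULL))
    sol <- inverse_kinematics_frame(model, kp, weights, q_prev,
                                    control = control, ctx = ctx)
    Q[i, ] <- sol$q[cn]
    rmse[i] <- sol$rmse
    converged[i] <- sol$converged
    valid[i] <- sol$valid
    if (sol$valid) q_prev <- sol$q
  }
  structure(list(q = Q, rmse = rmse, converged = converged, valid = valid),
            class = "ik_result")
}

# Accept either a trajectory3d or a raw frames x keypoints x 3 array.
trajectory_array <- function(traj) {
  if (inherits(traj, "trajectory3d")) {
    arr <- traj$pos
    if (!is.null(traj$valid)) {
      inv <- !traj$valid
      if (any(inv)) for (k in seq_len(dim(arr)[2]))
        arr[inv[, k], k, ] <- NA_real_
    }
    arr
  } else if (is.array(traj) && length(dim(traj)) == 3) traj
  else stop("traj must be a trajectory3d or a frames x keypoints x 3 array")
}

#' Extract named joint-angle signals from a solved pose series
#'
#' Returns the requested generalized coordinates as degree signals; coupled
#' DOFs (knee frontal/transverse angles, lumbar vertebrae) are evaluated
#' through their coupling functions. By default returns the right-side
#' lower-limb angle set.
#'
#' @param model The model the poses were solved with.
#' @param ik An `ik_result` (or a frames x coordinates matrix).
#' @param angles Character vector of DOF names.
#' @return Matrix frames x angles, degrees.
#' @export
compute_joint_angles <- function(model, ik,
                                 angles = c("hip_flexion_r",
                                            "hip_adduction_r",
                                            "hip_rotation_r",
                                            "knee_flexion_r",
                                            "ankle_flexion_r",
                                            "subtalar_r")) {
  Q <- if (inherits(ik, "ik_result")) ik$q else as.matrix(ik)
  out <- matrix(NA_real_, nrow(Q), length(angles),
                dimnames = list(NULL, angles))
  for (a in angles) {
    if (a %in% colnames(Q)) {
      out[, a] <- Q[, a]
    } else if (a %in% names(model$couplings)) {
      cp <- model$couplings[[a]]
      out[, a] <- stats::approx(cp$x, cp$y, xout = Q[, cp$master],
                                rule = 2)$y
    } else if (a %in% model$dofs$name &&
               model$dofs$type[match(a, model$dofs$name)] == "locked") {
      out[, a] <- model$dofs$value[match(a, model$dofs$name)]
    } else stop("unknown angle name: ", a)
  }
  out
}

#' Sagittal joint angles directly from segment vectors
#'
#' The model-free alternative to constrained inverse kinematics: hip, knee
#' and ankle flexion computed from the triangulated keypoints alone, as
#' planar angles of the thigh, shank and foot vectors in the sagittal
#' (X-Y) plane. Exact on clean keypoints of the shipped model when all
#' non-sagittal coordinates are zero; used as the comparison arm when
#' assessing how the skeletal model mitigates systematic keypoint offsets.
#'
#' @param model The model (provides the neutral foot pitch).
#' @param traj A `trajectory3d` or frames x keypoints x 3 array.
#' @param side `"r"` or `"l"`.
#' @return Matrix frames x c(hip_flexion, knee_flexion, ankle_flexion),
#'   degrees.
#' @export
direct_segment_angles <- function(model, traj, side = "r") {
  arr <- trajectory_array(traj)
  S <- toupper(side)
  hip <- arr[, paste0(S, "Hip"), ]; knee <- arr[, paste0(S, "Knee"), ]
  ank <- arr[, paste0(S, "Ankle"), ]; heel <- arr[, paste0(S, "Heel"), ]
  toe <- arr[, paste0(S, "BigToe"), ]
  thigh <- knee - hip; shank <- ank - knee; foot <- toe - heel
  th_t <- atan2(thigh[, 1], -thigh[, 2])
  th_s <- atan2(shank[, 1], -shank[, 2])
  th_f <- atan2(foot[, 2], foot[, 1])
  pl <- model$placements
  hl <- pl[pl$keypoint == paste0(S, "Heel"), ]
  tl <- pl[pl$keypoint == paste0(S, "BigToe"), ]
  foot_pitch0 <- atan2(tl$ly - hl$ly, tl$lx - hl$lx)
  cbind(hip_flexion = rad2deg(th_t),
        knee_flexion = rad2deg(th_t - th_s),
        ankle_flexion = rad2deg(th_f - th_s - foot_pitch0))
}

#' Functional joint center by least-squares sphere fitting
#'
#' Estimates a joint center from markers on a segment rotating about it:
#' each marker trajectory, expressed in the reference-segment frame, is fit
#' with an algebraic least-squares sphere; the joint center is the average
#' of the per-marker sphere centers. Near-planar marker paths leave one
#' direction unconstrained; that axis is flagged low-confidence.
#'
#' @param markers Array frames x markers x 3 (or matrix frames x 3 for one
#'   marker) of marker positions, meters.
#' @param ref_rotation Optional array 3 x 3 x frames of reference-segment
#'   world rotations; with `ref_position` (frames x 3), marker positions are
#'   first expressed in that (moving) reference frame.
#' @param ref_position See `ref_rotation`.
#' @return List with `center` (3-vector, reference frame), `radii`,
#'   `per_marker_centers`, `low_confidence_axis` (logical 3-vector).
#' @export
functional_joint_center <- function(markers, ref_rotation = NULL,
                                    ref_position = NULL) {
  if (is.matrix(markers)) markers <- array(markers,
                                           dim = c(nrow(markers), 1, 3))
  n <- dim(markers)[1]; m <- dim(markers)[2]
  if (n < 10) stop("need at least 10 frames of rotation")
  local <- markers
  if (!is.null(ref_rotation)) {
    for (t in seq_len(n)) {
      Rt <- ref_rotation[, , t]
      for (j in seq_len(m))
        local[t, j, ] <- as.numeric(crossprod(Rt, markers[t, j, ] -
                                                ref_position[t, ]))
    }
  }
  centers <- matrix(NA_real_, m, 3)
  radii <- numeric(m)
  min_sv_ratio <- Inf
  low_axis <- rep(FALSE, 3)
  for (j in seq_len(m)) {
    X <- local[, j, ]
    A <- cbind(2 * X, 1)
    b <- rowSums(X^2)
    sv <- svd(A)
    if (sv$d[4] / sv$d[1] < 1e-10) {
      # rank-deficient normal system: degenerate (planar/static) motion
      dirs <- sv$v[1:3, 4]
      low_axis <- low_axis | (abs(dirs) > 0.5)
      sol <- sv$v %*% ((crossprod(sv$u, b) / pmax(sv$d, sv$d[1] * 1e-10)))
    } else {
      sol <- sv$v %*% (crossprod(sv$u, b) / sv$d)
    }
    centers[j, ] <- sol[1:3]
    radii[j] <- sqrt(max(sol[4] + sum(sol[1:3]^2), 0))
    # spread of the marker path: a static marker cannot define a sphere
    if (max(apply(X, 2, stats::sd)) < 1e-9)
      stop("degenerate motion: marker ", j, " does not move")
    min_sv_ratio <- min(min_sv_ratio, sv$d[4] / sv$d[1])
  }
  list(center = colMeans(centers), radii = radii,
       per_marker_centers = centers, low_confidence_axis = low_axis)
}
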
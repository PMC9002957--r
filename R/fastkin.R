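# Compiled kinematics core. skeletal_model() attaches a flat index-based
# context (built once) so that per-frame forward kinematics and the
# analytic chain-rule Jacobian run without data.frame overhead; the IK
# solver leans on both. Internal units: radians / meters.

lin_interp <- function(xk, yk, v) {
  # piecewise-linear, constant beyond the end knots
  if (v <= xk[1]) return(yk[1])
  n <- length(xk)
  if (v >= xk[n]) return(yk[n])
  i <- findInterval(v, xk)
  yk[i] + (yk[i + 1] - yk[i]) * (v - xk[i]) / (xk[i + 1] - xk[i])
}

lin_slope <- function(xk, yk, v) {
  n <- length(xk)
  if (v < xk[1] || v > xk[n]) return(0)
  i <- min(findInterval(v, xk), n - 1)
  (yk[i + 1] - yk[i]) / (xk[i + 1] - xk[i])
}

build_model_ctx <- function(model) {
  segs <- model$segments
  dofs <- model$dofs
  nseg <- nrow(segs)
  seg_id <- stats::setNames(seq_len(nseg), segs$name)
  parent <- seg_id[segs$parent]
  names(parent) <- NULL
  off <- as.matrix(segs[, c("ox", "oy", "oz")])
  topo <- seg_id[model$topo]

  ndof <- nrow(dofs)
  ax_raw <- dofs$axis
  neg <- !is.na(ax_raw) & startsWith(ax_raw, "-")
  ax <- sub("^-", "", ax_raw)
  kind <- ifelse(is.na(ax), NA_integer_, ifelse(ax %in% c("tx", "ty", "tz"),
                                                1L, 0L))
  axis_idx <- match(ax, c("x", "y", "z"))
  tr <- which(!is.na(kind) & kind == 1L)
  axis_idx[tr] <- match(ax[tr], c("tx", "ty", "tz"))
  sign <- ifelse(neg, -1, 1)
  type <- match(dofs$type, c("free", "limited", "locked", "coupled"))
  dof_seg <- seg_id[dofs$segment]
  names(dof_seg) <- NULL
  q_names <- dofs$name[type %in% c(1L, 2L)]
  qidx <- match(dofs$name, q_names)
  is_rot_dof <- is.na(kind) | kind == 0L
  locked_val <- ifelse(type == 3L,
                       ifelse(is_rot_dof, deg2rad(dofs$value), dofs$value),
                       NA_real_)
  master <- rep(NA_integer_, ndof)
  knots_x <- knots_y <- vector("list", ndof)
  for (i in which(type == 4L)) {
    cp <- model$couplings[[dofs$name[i]]]
    master[i] <- match(cp$master, dofs$name)
    # couplings are angle-to-angle: store knots in radians
    knots_x[[i]] <- deg2rad(cp$x)
    knots_y[[i]] <- deg2rad(cp$y)
  }
  seg_dofs <- lapply(seq_len(nseg), function(s)
    which(!is.na(dof_seg) & dof_seg == s))

  # ancestor-or-self incidence
  anc <- matrix(FALSE, nseg, nseg)
  for (s in seq_len(nseg)) {
    cur <- s
    while (!is.na(cur)) { anc[cur, s] <- TRUE; cur <- parent[cur] }
  }
  kp_seg <- seg_id[model$placements$segment]
  names(kp_seg) <- NULL
  kp_loc <- as.matrix(model$placements[, c("lx", "ly", "lz")])
  kp_names <- model$placements$keypoint
  mk_seg <- seg_id[model$markers$segment]
  names(mk_seg) <- NULL
  mk_loc <- as.matrix(model$markers[, c("lx", "ly", "lz")])

  nq <- length(q_names)
  q_is_rot <- is_rot_dof[match(q_names, dofs$name)]
  bl <- coordinate_bounds(model)
  lower <- ifelse(q_is_rot, deg2rad(bl$lo[q_names]), bl$lo[q_names])
  upper <- ifelse(q_is_rot, deg2rad(bl$hi[q_names]), bl$hi[q_names])

  # per-keypoint incidence of each attached dof's segment subtree
  kp_of_dof <- lapply(seq_len(ndof), function(d) {
    if (is.na(dof_seg[d])) integer(0)
    else which(anc[dof_seg[d], kp_seg])
  })

  list(nseg = nseg, parent = parent, off = off, topo = topo,
       ndof = ndof, dof_names = dofs$name, dof_seg = dof_seg, kind = kind,
       axis_idx = axis_idx, sign = sign, type = type, qidx = qidx,
       locked_val = locked_val, master = master, knots_x = knots_x,
       knots_y = knots_y, seg_dofs = seg_dofs, anc = anc,
       kp_seg = kp_seg, kp_loc = kp_loc, kp_names = kp_names,
       mk_seg = mk_seg, mk_loc = mk_loc, mk_names = model$markers$name,
       nq = nq, q_names = q_names, q_is_rot = q_is_rot,
       lower = lower, upper = upper, kp_of_dof = kp_of_dof,
       is_rot_dof = is_rot_dof)
}

model_ctx <- function(model) {
  model$ctx %||% build_model_ctx(model)
}

# resolve all internal DOF values from internal coordinates par (radians/m)
resolve_vals <- function(ctx, par) {
  vals <- numeric(ctx$ndof)
  qq <- ctx$type %in% c(1L, 2L)
  vals[qq] <- par[ctx$qidx[qq]]
  lk <- ctx$type == 3L
  vals[lk] <- ctx$locked_val[lk]
  for (d in which(ctx$type == 4L))
    vals[d] <- lin_interp(ctx$knots_x[[d]], ctx$knots_y[[d]],
                          vals[ctx$master[d]])
  vals
}

# Forward kinematics (+ optional analytic Jacobian of keypoint positions
# with respect to the internal coordinate vector).
fk_eval <- function(ctx, par, jacobian = FALSE, markers = FALSE) {
  vals <- resolve_vals(ctx, par)
  Rs <- vector("list", ctx$nseg)
  ps <- matrix(0, ctx$nseg, 3)
  dof_axis_w <- if (jacobian) matrix(0, ctx$ndof, 3)
  dof_org_w <- if (jacobian) matrix(0, ctx$ndof, 3)
  for (s in ctx$topo) {
    pa <- ctx$parent[s]
    if (is.na(pa)) {
      R <- diag(3); p <- c(0, 0, 0)
    } else {
      R <- Rs[[pa]]
      p <- ps[pa, ] + as.numeric(R %*% ctx$off[s, ])
    }
    for (d in ctx$seg_dofs[[s]]) {
      ai <- ctx$axis_idx[d]
      if (ctx$kind[d] == 1L) {            # translation
        axis_w <- ctx$sign[d] * R[, ai]
        p <- p + axis_w * vals[d]
        if (jacobian) dof_axis_w[d, ] <- axis_w
      } else {                            # rotation about local axis
        axis_w <- ctx$sign[d] * R[, ai]
        if (jacobian) { dof_axis_w[d, ] <- axis_w; dof_org_w[d, ] <- p }
        R <- R %*% rot_axis(c("x", "y", "z")[ai],
                            ctx$sign[d] * vals[d])
      }
    }
    Rs[[s]] <- R
    ps[s, ] <- p
  }
  nk <- length(ctx$kp_seg)
  kp <- matrix(NA_real_, nk, 3, dimnames = list(ctx$kp_names,
                                                c("x", "y", "z")))
  for (k in seq_len(nk)) {
    s <- ctx$kp_seg[k]
    kp[k, ] <- ps[s, ] + as.numeric(Rs[[s]] %*% ctx$kp_loc[k, ])
  }
  out <- list(kp = kp, Rs = Rs, ps = ps, vals = vals)
  if (markers) {
    nm <- length(ctx$mk_seg)
    mk <- matrix(NA_real_, nm, 3, dimnames = list(ctx$mk_names,
                                                  c("x", "y", "z")))
    for (k in seq_len(nm)) {
      s <- ctx$mk_seg[k]
      mk[k, ] <- ps[s, ] + as.numeric(Rs[[s]] %*% ctx$mk_loc[k, ])
    }
    out$mk <- mk
  }
  if (jacobian) {
    J <- array(0, c(nk, 3, ctx$nq))
    add_dof <- function(J, d, qi, scale) {
      kps <- ctx$kp_of_dof[[d]]
      if (!length(kps)) return(J)
      if (ctx$kind[d] == 1L) {
        for (k in kps) J[k, , qi] <- J[k, , qi] + scale * dof_axis_w[d, ]
      } else {
        a <- dof_axis_w[d, ]; o <- dof_org_w[d, ]
        for (k in kps) {
          r <- kp[k, ] - o
          J[k, , qi] <- J[k, , qi] + scale * cross3(a, r)
        }
      }
      J
    }
    for (d in seq_len(ctx$ndof)) {
      if (is.na(ctx$dof_seg[d])) next
      if (ctx$type[d] %in% c(1L, 2L)) {
        J <- add_dof(J, d, ctx$qidx[d], 1)
      } else if (ctx$type[d] == 4L) {
        mi <- ctx$master[d]
        if (ctx$type[mi] %in% c(1L, 2L)) {
          sl <- lin_slope(ctx$knots_x[[d]], ctx$knots_y[[d]],
                          vals[mi])
          if (sl != 0) J <- add_dof(J, d, ctx$qidx[mi], sl)
        }
      }
    }
    out$J <- J
  }
  out
}
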
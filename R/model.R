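# Articulated skeletal model: a tree of rigid segments rooted at the pelvis,
# with typed degrees of freedom (free / locked / limited / coupled), keypoint
# placements for markerless tracking and anatomical-marker placements for the
# marker-based reference channel.

#' Construct a skeletal model
#'
#' Low-level constructor; most users want [default_model()].
#'
#' @param segments data.frame with columns `name`, `parent` (NA for the root),
#'   `ox`, `oy`, `oz` — the joint location in the parent segment's frame
#'   (meters).
#' @param dofs data.frame with columns `name`, `segment` (NA for virtual
#'   master coordinates), `axis` (`tx`,`ty`,`tz` or `x`,`y`,`z`, optionally
#'   prefixed `-`), `type` (`free`, `locked`, `limited`, `coupled`),
#'   `value` (locked value, degrees), `lo`, `hi` (limits, degrees or meters).
#'   Rotations at a joint are composed in row order.
#' @param placements data.frame with columns `keypoint`, `segment`,
#'   `lx`, `ly`, `lz` (meters, segment frame).
#' @param markers Optional data.frame of anatomical/cluster markers with
#'   columns `name`, `segment`, `lx`, `ly`, `lz`, `joint`, `type`.
#' @param couplings Named list; for each coupled DOF, a list with `master`
#'   (DOF name) and knot vectors `x`, `y` (degrees) interpolated piecewise
#'   linearly (constant beyond the end knots).
#' @param measurement_pairs Named list mapping segment name to a list of
#'   keypoint pairs (character length-2) used by measurement-based scaling.
#' @return An object of class `skeletal_model`.
#' @export
skeletal_model <- function(segments, dofs, placements, markers = NULL,
                           couplings = list(), measurement_pairs = list()) {
  segments <- as.data.frame(segments); dofs <- as.data.frame(dofs)
  placements <- as.data.frame(placements)
  root <- segments$name[is.na(segments$parent)]
  if (length(root) != 1)
    stop("segment graph must have exactly one root (the pelvis)")
  for (p in segments$parent[!is.na(segments$parent)])
    if (!p %in% segments$name) stop("unknown parent segment: ", p)
  # tree check: walking up from every segment must reach the root
  for (s in segments$name) {
    seen <- character(); cur <- s
    while (!is.na(cur)) {
      if (cur %in% seen) stop("segment graph contains a cycle at ", cur)
      seen <- c(seen, cur)
      cur <- segments$parent[match(cur, segments$name)]
    }
  }
  bad_lim <- dofs$type == "limited" & !(dofs$lo < dofs$hi)
  if (any(bad_lim, na.rm = TRUE))
    stop("limited DOFs need lo < hi: ",
         paste(dofs$name[which(bad_lim)], collapse = ", "))
  for (d in dofs$name[dofs$type == "coupled"]) {
    cp <- couplings[[d]]
    if (is.null(cp) || !cp$master %in% dofs$name)
      stop("coupled DOF ", d, " lacks a valid master coupling")
  }
  if (is.null(markers))
    markers <- data.frame(name = character(), segment = character(),
                          lx = numeric(), ly = numeric(), lz = numeric(),
                          joint = character(), type = character())
  m <- structure(list(segments = segments, dofs = dofs,
                      placements = placements, markers = markers,
                      couplings = couplings,
                      measurement_pairs = measurement_pairs,
                      root = root),
                 class = "skeletal_model")
  m$topo <- topo_order(m)
  m$ctx <- build_model_ctx(m)   # compiled index cache for fast kinematics
  m
}

topo_order <- function(model) {
  segs <- model$segments
  ordered <- model$root
  remaining <- setdiff(segs$name, ordered)
  while (length(remaining)) {
    nxt <- remaining[segs$parent[match(remaining, segs$name)] %in% ordered]
    if (!length(nxt)) stop("segment graph is not connected")
    ordered <- c(ordered, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  ordered
}

#' Names of the model's generalized coordinates
#'
#' Free and limited DOFs, in model order; locked and coupled DOFs are not
#' coordinates (they are substituted automatically during kinematics).
#'
#' @param model A [skeletal_model()].
#' @return Character vector of coordinate names.
#' @export
coordinate_names <- function(model) {
  model$dofs$name[model$dofs$type %in% c("free", "limited")]
}

# Coordinate bounds in public units (degrees / meters); Inf for free DOFs.
coordinate_bounds <- function(model) {
  d <- model$dofs[model$dofs$type %in% c("free", "limited"), ]
  lo <- ifelse(d$type == "limited", d$lo, -Inf)
  hi <- ifelse(d$type == "limited", d$hi, Inf)
  list(lo = stats::setNames(lo, d$name), hi = stats::setNames(hi, d$name))
}

#' Evaluate a coupling function of the model
#'
#' @param model A [skeletal_model()].
#' @param dof Name of a coupled DOF.
#' @param master_value Master DOF value(s) in degrees.
#' @return Coupled DOF value(s) in degrees.
#' @export
coupling_value <- function(model, dof, master_value) {
  cp <- model$couplings[[dof]]
  if (is.null(cp)) stop(dof, " is not a coupled DOF")
  stats::approx(cp$x, cp$y, xout = master_value, rule = 2)$y
}

#' The shipped full-body skeletal model
#'
#' A simplified humanoid: pelvis root, a five-link lumbar stack whose
#' vertebrae each carry one fifth of the total lumbar flexion, torso, head,
#' and three-segment limbs. Constraint set: wrist flexion and deviation
#' locked at 0 deg; forearm pronation/supination locked at 90 deg; pelvis
#' translation and the subtalar angles unlocked; hip flexion limited to
#' 150 deg; knee abduction/adduction and internal/external rotation coupled
#' to knee flexion by piecewise-linear splines that vanish at 0 deg flexion.
#' Keypoint placements cover a 21-point body layout (eyes and ears excluded);
#' anatomical markers (malleoli, epicondyles, styloids, thigh clusters,
#' pelvis landmarks) support a marker-based reference channel whose landmark
#' midpoints coincide with the model's joint centers.
#'
#' @return A [skeletal_model()].
#' @export
default_model <- function() {
  seg <- function(name, parent, o) data.frame(name = name, parent = parent,
                                              ox = o[1], oy = o[2], oz = o[3])
  segments <- rbind(
    seg("pelvis", NA, c(0, 0, 0)),
    seg("lumbar1", "pelvis", c(-0.03, 0.08, 0)),
    seg("lumbar2", "lumbar1", c(0, 0.035, 0)),
    seg("lumbar3", "lumbar2", c(0, 0.035, 0)),
    seg("lumbar4", "lumbar3", c(0, 0.035, 0)),
    seg("lumbar5", "lumbar4", c(0, 0.035, 0)),
    seg("torso", "lumbar5", c(0, 0.035, 0)),
    seg("head", "torso", c(0, 0.47, 0)),
    seg("femur_r", "pelvis", c(0, -0.07, 0.09)),
    seg("tibia_r", "femur_r", c(0, -0.42, 0)),
    seg("foot_r", "tibia_r", c(0, -0.43, 0)),
    seg("femur_l", "pelvis", c(0, -0.07, -0.09)),
    seg("tibia_l", "femur_l", c(0, -0.42, 0)),
    seg("foot_l", "tibia_l", c(0, -0.43, 0)),
    seg("upperarm_r", "torso", c(0, 0.42, 0.20)),
    seg("forearm_r", "upperarm_r", c(0, -0.30, 0)),
    seg("hand_r", "forearm_r", c(0, -0.26, 0)),
    seg("upperarm_l", "torso", c(0, 0.42, -0.20)),
    seg("forearm_l", "upperarm_l", c(0, -0.30, 0)),
    seg("hand_l", "forearm_l", c(0, -0.26, 0)))

  dof <- function(name, segment, axis, type, value = NA_real_,
                  lo = NA_real_, hi = NA_real_)
    data.frame(name = name, segment = segment, axis = axis, type = type,
               value = value, lo = lo, hi = hi)
  side <- function(s, zsgn) rbind(
    dof(paste0("hip_flexion_", s), paste0("femur_", s), "z", "limited",
        lo = -40, hi = 150),
    dof(paste0("hip_adduction_", s), paste0("femur_", s),
        if (zsgn > 0) "x" else "-x", "limited", lo = -50, hi = 40),
    dof(paste0("hip_rotation_", s), paste0("femur_", s),
        if (zsgn > 0) "y" else "-y", "limited", lo = -45, hi = 45),
    dof(paste0("knee_flexion_", s), paste0("tibia_", s), "-z", "limited",
        lo = 0, hi = 150),
    dof(paste0("knee_adduction_", s), paste0("tibia_", s),
        if (zsgn > 0) "x" else "-x", "coupled"),
    dof(paste0("knee_rotation_", s), paste0("tibia_", s),
        if (zsgn > 0) "y" else "-y", "coupled"),
    dof(paste0("ankle_flexion_", s), paste0("foot_", s), "z", "limited",
        lo = -55, hi = 45),
    dof(paste0("subtalar_", s), paste0("foot_", s),
        if (zsgn > 0) "x" else "-x", "limited", lo = -35, hi = 35),
    dof(paste0("shoulder_flexion_", s), paste0("upperarm_", s), "z",
        "limited", lo = -60, hi = 180),
    dof(paste0("shoulder_adduction_", s), paste0("upperarm_", s),
        if (zsgn > 0) "x" else "-x", "limited", lo = -180, hi = 30),
    dof(paste0("elbow_flexion_", s), paste0("forearm_", s), "z", "limited",
        lo = 0, hi = 150),
    dof(paste0("pro_sup_", s), paste0("forearm_", s), "y", "locked",
        value = 90),
    dof(paste0("wrist_flexion_", s), paste0("hand_", s), "z", "locked",
        value = 0),
    dof(paste0("wrist_deviation_", s), paste0("hand_", s), "x", "locked",
        value = 0))
  dofs <- rbind(
    dof("pelvis_tx", "pelvis", "tx", "free"),
    dof("pelvis_ty", "pelvis", "ty", "free"),
    dof("pelvis_tz", "pelvis", "tz", "free"),
    dof("pelvis_tilt", "pelvis", "z", "limited", lo = -90, hi = 90),
    dof("pelvis_list", "pelvis", "x", "limited", lo = -90, hi = 90),
    dof("pelvis_rotation", "pelvis", "y", "limited", lo = -180, hi = 180),
    dof("lumbar_flexion", NA, NA, "limited", lo = -30, hi = 90),
    dof("lumbar1_flexion", "lumbar1", "z", "coupled"),
    dof("lumbar2_flexion", "lumbar2", "z", "coupled"),
    dof("lumbar3_flexion", "lumbar3", "z", "coupled"),
    dof("lumbar4_flexion", "lumbar4", "z", "coupled"),
    dof("lumbar5_flexion", "lumbar5", "z", "coupled"),
    side("r", +1), side("l", -1))

  # knee couplings: small frontal/transverse rotations tied to flexion,
  # zero at full extension
  knee_add <- list(x = c(0, 60, 150), y = c(0, -2.5, -5))
  knee_rot <- list(x = c(0, 60, 150), y = c(0, 8, 14))
  lumbar_cp <- list(x = c(-90, 90), y = c(-18, 18))   # 1/5 of total flexion
  couplings <- list(
    knee_adduction_r = c(list(master = "knee_flexion_r"), knee_add),
    knee_rotation_r  = c(list(master = "knee_flexion_r"), knee_rot),
    knee_adduction_l = c(list(master = "knee_flexion_l"), knee_add),
    knee_rotation_l  = c(list(master = "knee_flexion_l"), knee_rot),
    lumbar1_flexion = c(list(master = "lumbar_flexion"), lumbar_cp),
    lumbar2_flexion = c(list(master = "lumbar_flexion"), lumbar_cp),
    lumbar3_flexion = c(list(master = "lumbar_flexion"), lumbar_cp),
    lumbar4_flexion = c(list(master = "lumbar_flexion"), lumbar_cp),
    lumbar5_flexion = c(list(master = "lumbar_flexion"), lumbar_cp))

  kp <- function(keypoint, segment, l) data.frame(keypoint = keypoint,
                                                  segment = segment,
                                                  lx = l[1], ly = l[2], lz = l[3])
  placements <- rbind(
    kp("Nose", "head", c(0.10, 0.05, 0)),
    kp("Head", "head", c(0, 0.12, 0)),
    kp("Neck", "torso", c(0, 0.45, 0)),
    kp("RShoulder", "torso", c(0, 0.42, 0.20)),
    kp("LShoulder", "torso", c(0, 0.42, -0.20)),
    kp("RElbow", "upperarm_r", c(0, -0.30, 0)),
    kp("LElbow", "upperarm_l", c(0, -0.30, 0)),
    kp("RWrist", "forearm_r", c(0, -0.26, 0)),
    kp("LWrist", "forearm_l", c(0, -0.26, 0)),
    kp("RHip", "pelvis", c(0, -0.07, 0.09)),
    kp("LHip", "pelvis", c(0, -0.07, -0.09)),
    kp("RKnee", "femur_r", c(0, -0.42, 0)),
    kp("LKnee", "femur_l", c(0, -0.42, 0)),
    kp("RAnkle", "tibia_r", c(0, -0.43, 0)),
    kp("LAnkle", "tibia_l", c(0, -0.43, 0)),
    kp("RHeel", "foot_r", c(-0.05, -0.05, 0)),
    kp("LHeel", "foot_l", c(-0.05, -0.05, 0)),
    kp("RBigToe", "foot_r", c(0.16, -0.06, -0.02)),
    kp("LBigToe", "foot_l", c(0.16, -0.06, 0.02)),
    kp("RSmallToe", "foot_r", c(0.13, -0.06, 0.04)),
    kp("LSmallToe", "foot_l", c(0.13, -0.06, -0.04)))

  mk <- function(name, segment, l, joint = NA_character_,
                 type = "anatomical")
    data.frame(name = name, segment = segment, lx = l[1], ly = l[2],
               lz = l[3], joint = joint, type = type)
  mside <- function(S, s, zsgn) rbind(
    mk(paste0(S, "KneeMed"), paste0("femur_", s),
       c(0, -0.42, -0.05 * zsgn), paste0(S, "Knee")),
    mk(paste0(S, "KneeLat"), paste0("femur_", s),
       c(0, -0.42, 0.05 * zsgn), paste0(S, "Knee")),
    mk(paste0(S, "AnkleMed"), paste0("tibia_", s),
       c(0, -0.43, -0.04 * zsgn), paste0(S, "Ankle")),
    mk(paste0(S, "AnkleLat"), paste0("tibia_", s),
       c(0, -0.43, 0.04 * zsgn), paste0(S, "Ankle")),
    mk(paste0(S, "WristMed"), paste0("forearm_", s),
       c(0, -0.26, -0.03 * zsgn), paste0(S, "Wrist")),
    mk(paste0(S, "WristLat"), paste0("forearm_", s),
       c(0, -0.26, 0.03 * zsgn), paste0(S, "Wrist")),
    mk(paste0(S, "Thigh1"), paste0("femur_", s),
       c(0.04, -0.15, 0.05 * zsgn), type = "cluster"),
    mk(paste0(S, "Thigh2"), paste0("femur_", s),
       c(-0.02, -0.24, 0.06 * zsgn), type = "cluster"),
    mk(paste0(S, "Thigh3"), paste0("femur_", s),
       c(0.05, -0.31, 0.02 * zsgn), type = "cluster"),
    mk(paste0(S, "ElbMed"), paste0("upperarm_", s),
       c(0, -0.30, -0.04 * zsgn), paste0(S, "Elbow")),
    mk(paste0(S, "ElbLat"), paste0("upperarm_", s),
       c(0, -0.30, 0.04 * zsgn), paste0(S, "Elbow")),
    mk(paste0(S, "ShoFront"), "torso", c(0.04, 0.42, 0.20 * zsgn),
       paste0(S, "Shoulder")),
    mk(paste0(S, "ShoBack"), "torso", c(-0.04, 0.42, 0.20 * zsgn),
       paste0(S, "Shoulder")),
    mk(paste0(S, "Heel"), paste0("foot_", s), c(-0.05, -0.05, 0),
       paste0(S, "Heel")),
    mk(paste0(S, "Toe"), paste0("foot_", s), c(0.16, -0.06, -0.02 * zsgn),
       paste0(S, "BigToe")),
    mk(paste0(S, "ASI"), "pelvis", c(0.08, 0.02, 0.12 * zsgn)),
    mk(paste0(S, "PSI"), "pelvis", c(-0.10, 0.02, 0.05 * zsgn)))
  markers <- rbind(mside("R", "r", +1), mside("L", "l", -1),
                   mk("C7", "torso", c(0, 0.45, 0), "Neck"),
                   mk("HeadTop", "head", c(0, 0.12, 0), "Head"))

  measurement_pairs <- list(
    pelvis = list(c("RHip", "LHip")),
    femur_r = list(c("RHip", "RKnee")), femur_l = list(c("LHip", "LKnee")),
    tibia_r = list(c("RKnee", "RAnkle")), tibia_l = list(c("LKnee", "LAnkle")),
    foot_r = list(c("RHeel", "RBigToe")), foot_l = list(c("LHeel", "LBigToe")),
    torso = list(c("Neck", "RHip"), c("Neck", "LHip")),
    head = list(c("Neck", "Head")),
    upperarm_r = list(c("RShoulder", "RElbow")),
    upperarm_l = list(c("LShoulder", "LElbow")),
    forearm_r = list(c("RElbow", "RWrist")),
    forearm_l = list(c("LElbow", "LWrist")))

  skeletal_model(segments, dofs, placements, markers, couplings,
                 measurement_pairs)
}

#' Neutral (zero) pose of a model
#'
#' All coordinates zero except the pelvis height, which is set so the feet
#' rest near the floor.
#'
#' @param model A [skeletal_model()].
#' @param pelvis_height Pelvis origin height in meters.
#' @return Named coordinate vector (degrees / meters).
#' @export
neutral_pose <- function(model, pelvis_height = 0.99) {
  q <- stats::setNames(numeric(length(coordinate_names(model))),
                       coordinate_names(model))
  if ("pelvis_ty" %in% names(q)) q["pelvis_ty"] <- pelvis_height
  q
}

#' Write / read a skeletal model as YAML
#'
#' @param model A [skeletal_model()].
#' @param path File path.
#' @return `read_model` returns a [skeletal_model()].
#' @export
write_model <- function(model, path) {
  rows <- function(df) lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(v) if (is.na(v)) NULL else unname(v))
  })
  doc <- list(
    segments = rows(model$segments),
    dofs = rows(model$dofs),
    placements = rows(model$placements),
    markers = rows(model$markers),
    couplings = model$couplings,
    measurement_pairs = lapply(model$measurement_pairs,
                               function(ps) lapply(ps, as.list)))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x) || (is.character(x) && x == "NA"))
    NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x) || identical(x, "NA"))
    NA_character_ else as.character(x)
  segments <- do.call(rbind, lapply(doc$segments, function(s)
    data.frame(name = s$name, parent = chr(s$parent), ox = num(s$ox),
               oy = num(s$oy), oz = num(s$oz))))
  dofs <- do.call(rbind, lapply(doc$dofs, function(d)
    data.frame(name = d$name, segment = chr(d$segment), axis = chr(d$axis),
               type = d$type, value = num(d$value), lo = num(d$lo),
               hi = num(d$hi))))
  placements <- do.call(rbind, lapply(doc$placements, function(p)
    data.frame(keypoint = p$keypoint, segment = p$segment, lx = num(p$lx),
               ly = num(p$ly), lz = num(p$lz))))
  markers <- if (length(doc$markers))
    do.call(rbind, lapply(doc$markers, function(p)
      data.frame(name = p$name, segment = p$segment, lx = num(p$lx),
                 ly = num(p$ly), lz = num(p$lz), joint = chr(p$joint),
                 type = p$type)))
  else NULL
  couplings <- lapply(doc$couplings, function(cp)
    list(master = cp$master, x = as.numeric(cp$x), y = as.numeric(cp$y)))
  pairs <- lapply(doc$measurement_pairs,
                  function(ps) lapply(ps, function(p) unlist(p)))
  skeletal_model(segments, dofs, placements, markers, couplings, pairs)
}
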
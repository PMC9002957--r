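# Readers/writers for the interchange formats of the markerless-kinematics
# ecosystem: per-frame OpenPose-dialect JSON keypoints, TRC marker
# trajectories and MOT joint-coordinate files (tab-separated OpenSim-style
# dialects), and cycle-metadata CSV.

#' Write per-camera OpenPose-dialect JSON files
#'
#' One subdirectory per camera, one JSON file per frame:
#' `{"people":[{"pose_keypoints_2d":[x1,y1,c1,...]}]}`.
#'
#' @param obs A `keypoint_observations` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_openpose_json <- function(obs, dir) {
  n <- dim(obs$u)[1]; n_c <- dim(obs$u)[2]; n_k <- dim(obs$u)[3]
  for (c_ in seq_len(n_c)) {
    cam_dir <- file.path(dir, obs$cameras[c_] %||% sprintf("cam_%02d", c_))
    dir.create(cam_dir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_len(n)) {
      triplets <- as.numeric(rbind(
        ifelse(is.na(obs$u[t, c_, ]), 0, obs$u[t, c_, ]),
        ifelse(is.na(obs$v[t, c_, ]), 0, obs$v[t, c_, ]),
        obs$conf[t, c_, ]))
      doc <- list(version = 1.3,
                  people = list(list(pose_keypoints_2d = triplets)))
      jsonlite::write_json(doc, file.path(cam_dir,
                                          sprintf("frame_%06d.json", t - 1)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Read per-camera OpenPose-dialect JSON keypoints
#'
#' Expects one subdirectory per camera, each holding one JSON file per
#' frame (sorted by name). Keypoints with confidence 0 are treated as
#' missing. In strict mode a file with several people is an error;
#' otherwise the first person is taken.
#'
#' @param dir Directory of per-camera subdirectories.
#' @param keypoint_names Configured keypoint name list; validated against
#'   the triplet count in each file.
#' @param frame_rate Sampling rate to record, Hz.
#' @param strict Error on multi-person files (default TRUE).
#' @return A `keypoint_observations` object.
#' @export
read_openpose_json <- function(dir, keypoint_names = NULL, frame_rate = 30,
                               strict = TRUE) {
  cams <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(cams)) stop("no per-camera subdirectories found in ", dir)
  files <- lapply(cams, function(d) sort(list.files(d, "\\.json$",
                                                    full.names = TRUE)))
  counts <- lengths(files)
  if (!length(files[[1]]) || any(counts == 0))
    stop("empty input: a camera directory contains no JSON frames")
  if (length(unique(counts)) != 1)
    stop("frame-count mismatch across cameras: ",
         paste(basename(cams), counts, sep = "=", collapse = ", "))
  n <- counts[1]; n_c <- length(cams)
  first <- jsonlite::read_json(files[[1]][1])
  k0 <- length(first$people[[1]]$pose_keypoints_2d) / 3
  if (is.null(keypoint_names))
    keypoint_names <- sprintf("kp_%02d", seq_len(k0))
  if (length(keypoint_names) != k0)
    stop("keypoint list length (", length(keypoint_names),
         ") does not match file triplets (", k0, ")")
  n_k <- length(keypoint_names)
  u <- v <- array(NA_real_, c(n, n_c, n_k),
                  dimnames = list(NULL, NULL, keypoint_names))
  conf <- array(0, c(n, n_c, n_k), dimnames = list(NULL, NULL, keypoint_names))
  for (c_ in seq_len(n_c)) {
    for (t in seq_len(n)) {
      doc <- tryCatch(jsonlite::read_json(files[[c_]][t]),
                      error = function(e)
                        stop("malformed JSON in ", files[[c_]][t], ": ",
                             conditionMessage(e)))
      people <- doc$people
      if (!length(people)) next
      if (length(people) > 1 && strict)
        stop("multiple people in ", files[[c_]][t],
             "; single-person scenes only")
      trip <- as.numeric(unlist(people[[1]]$pose_keypoints_2d))
      if (length(trip) != 3 * n_k)
        stop("keypoint count mismatch in ", files[[c_]][t])
      m <- matrix(trip, nrow = 3)
      keep <- m[3, ] > 0
      u[t, c_, keep] <- m[1, keep]
      v[t, c_, keep] <- m[2, keep]
      conf[t, c_, ] <- m[3, ]
    }
  }
  structure(list(u = u, v = v, conf = conf, keypoints = keypoint_names,
                 cameras = basename(cams), frame_rate = frame_rate),
            class = "keypoint_observations")
}

#' Write 3D trajectories as a TRC file
#'
#' Tab-separated, with the standard DataRate/CameraRate/NumFrames/Units
#' header, Frame# and Time columns, then X/Y/Z triplets per marker.
#'
#' @param pos Array frames x markers x 3 (meters) with marker dimnames, or
#'   a `trajectory3d` / `marker_set`.
#' @param path Output path.
#' @param frame_rate Hz (taken from the object when available).
#' @return `path`, invisibly.
#' @export
write_trc <- function(pos, path, frame_rate = 30) {
  if (inherits(pos, "trajectory3d") || inherits(pos, "marker_set")) {
    frame_rate <- pos$frame_rate %||% frame_rate
    pos <- pos$pos
  }
  n <- dim(pos)[1]; m <- dim(pos)[2]
  markers <- dimnames(pos)[[2]] %||% sprintf("M%02d", seq_len(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
          sep = "\t"),
    paste(frame_rate, frame_rate, n, m, "m", frame_rate, 1, n, sep = "\t"),
    paste(c("Frame#", "Time",
            as.character(rbind(markers, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                           rep(seq_len(m), each = 3))), collapse = "\t"),
    ""), con)
  times <- (seq_len(n) - 1) / frame_rate
  flat <- matrix(aperm(pos, c(3, 2, 1)), nrow = n, byrow = TRUE)
  for (t in seq_len(n))
    writeLines(paste(c(t, sprintf("%.6f", times[t]),
                       sprintf("%.6f", flat[t, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a TRC file
#'
#' @param path TRC path.
#' @return List: `pos` (frames x markers x 3, meters — mm inputs are
#'   converted with a warning), `markers`, `frame_rate`, `times`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("truncated TRC file: ", path,
                              " (", length(lines), " lines)")
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  frame_rate <- as.numeric(hdr$DataRate)
  units <- hdr$Units %||% "m"
  marker_row <- strsplit(lines[4], "\t")[[1]]
  markers <- marker_row[seq(3, length(marker_row), by = 3)]
  markers <- markers[nzchar(markers)]
  m <- length(markers)
  data_lines <- lines[-(1:6)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  if (!n) stop("TRC file has no data rows: ", path)
  pos <- array(NA_real_, c(n, m, 3), dimnames = list(NULL, markers,
                                                     c("x", "y", "z")))
  times <- numeric(n)
  for (t in seq_len(n)) {
    f <- as.numeric(strsplit(data_lines[t], "\t")[[1]])
    if (length(f) < 2 + 3 * m)
      stop("parse error in TRC at data line ", t, " of ", path)
    times[t] <- f[2]
    pos[t, , ] <- matrix(f[-(1:2)][seq_len(3 * m)], m, 3, byrow = TRUE)
  }
  if (tolower(units) == "mm") {
    warning("TRC units are mm; converting to meters")
    pos <- pos / 1000
  }
  list(pos = pos, markers = markers, frame_rate = frame_rate, times = times)
}

#' Write joint coordinates as a MOT file
#'
#' Header `name`, `nRows`/`nColumns`, `inDegrees=yes`, `endheader`, then a
#' time column followed by named coordinate columns.
#'
#' @param angles Matrix frames x coordinates (degrees), named columns.
#' @param path Output path.
#' @param frame_rate Hz.
#' @param name Motion name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mot <- function(angles, path, frame_rate = 30, name = "motion") {
  angles <- as.matrix(angles)
  n <- nrow(angles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", n),
               sprintf("nColumns=%d", ncol(angles) + 1),
               "inDegrees=yes",
               "endheader",
               paste(c("time", colnames(angles)), collapse = "\t")), con)
  times <- (seq_len(n) - 1) / frame_rate
  for (t in seq_len(n))
    writeLines(paste(c(sprintf("%.6f", times[t]),
                       sprintf("%.6f", angles[t, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a MOT file
#'
#' @param path MOT path.
#' @return List: `angles` (frames x coordinates, degrees — radian files are
#'   converted), `times`, `frame_rate`.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) stop("missing endheader in MOT file: ", path)
  in_degrees <- !any(grepl("^inDegrees\\s*=\\s*no", lines[1:end[1]],
                           ignore.case = TRUE))
  cols <- strsplit(lines[end[1] + 1], "\t")[[1]]
  data_lines <- lines[-(1:(end[1] + 1))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  vals <- matrix(NA_real_, n, length(cols))
  for (t in seq_len(n)) {
    f <- as.numeric(strsplit(data_lines[t], "\t")[[1]])
    if (length(f) != length(cols))
      stop("parse error in MOT at data line ", t, " of ", path)
    vals[t, ] <- f
  }
  times <- vals[, 1]
  angles <- vals[, -1, drop = FALSE]
  colnames(angles) <- cols[-1]
  if (!in_degrees) angles <- rad2deg(angles)
  fr <- if (n > 1) 1 / stats::median(diff(times)) else NA_real_
  list(angles = angles, times = times, frame_rate = fr)
}

#' Write / read cycle metadata as CSV
#'
#' Columns: cycle index, start frame, end frame, progression direction.
#'
#' @param events Event frame indices (cycle boundaries).
#' @param directions Per-cycle progression-axis sign (recycled).
#' @param path CSV path.
#' @return `read_cycles` returns a data.frame.
#' @export
write_cycles <- function(events, directions, path) {
  events <- as.integer(events)
  n_cyc <- max(length(events) - 1, 0)
  df <- data.frame(cycle = seq_len(n_cyc),
                   start = events[seq_len(n_cyc)],
                   end = events[seq_len(n_cyc) + 1],
                   direction = rep_len(directions, max(n_cyc, 1))[seq_len(n_cyc)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  utils::read.csv(path)
}
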
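#' Camera parameters for a pinhole camera
#'
#' Bundles the intrinsics and pose of one virtual (or calibrated real) camera.
#' The extrinsics map world coordinates to camera coordinates as
#' `x_cam = R x_world + t`; the camera looks along its +Z axis.
#'
#' @param focal Length-2 numeric, focal lengths (fx, fy) in pixels.
#' @param center Length-2 numeric, principal point (cx, cy) in pixels.
#' @param rotation 3x3 world-to-camera rotation matrix (orthonormal, det +1).
#' @param translation Length-3 numeric, camera translation in meters.
#' @param image_size Length-2 numeric, image (width, height) in pixels.
#' @param name Optional camera name.
#' @return An object of class `camera_params`.
#' @export
camera_params <- function(focal, center, rotation, translation,
                          image_size = c(1000, 1000), name = NULL) {
  focal <- as.numeric(focal); center <- as.numeric(center)
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (any(focal <= 0)) stop("focal lengths must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  if (center[1] < 0 || center[1] > image_size[1] ||
      center[2] < 0 || center[2] > image_size[2])
    stop("principal point must lie inside the image bounds")
  structure(list(focal = focal, center = center, rotation = rotation,
                 translation = translation, image_size = as.numeric(image_size),
                 name = name),
            class = "camera_params")
}

#' Build a circular multi-camera rig aimed at a common target
#'
#' Places `n_cameras` evenly on a circle of given radius around the target
#' (in the horizontal X-Z plane, world Y up) at the requested heights, each
#' oriented so its optical axis passes through the target. A converging
#' circular rig is the standard laboratory arrangement for markerless
#' multi-view capture.
#'
#' @param n_cameras Number of cameras (>= 2; triangulation needs two views).
#' @param radius Circle radius in meters (> 0).
#' @param heights Camera heights in meters; recycled to `n_cameras`.
#' @param target Length-3 world point all cameras aim at.
#' @param focal,image_size Shared intrinsics for every camera.
#' @return A list of [camera_params()] objects (class `camera_rig`).
#' @examples
#' rig <- make_rig(8, radius = 4)
#' length(rig)
#' @export
make_rig <- function(n_cameras, radius, heights = 1.2, target = c(0, 1, 0),
                     focal = c(900, 900), image_size = c(1000, 1000)) {
  if (n_cameras < 2)
    stop("at least 2 cameras are required for triangulation")
  if (radius <= 0) stop("radius must be positive")
  heights <- rep_len(as.numeric(heights), n_cameras)
  target <- as.numeric(target)
  cams <- vector("list", n_cameras)
  for (i in seq_len(n_cameras)) {
    theta <- 2 * pi * (i - 1) / n_cameras
    pos <- c(target[1] + radius * cos(theta), heights[i],
             target[3] + radius * sin(theta))
    z_axis <- normalize3(target - pos)              # optical axis
    up <- c(0, 1, 0)
    x_axis <- normalize3(cross3(up, z_axis))
    y_axis <- cross3(z_axis, x_axis)
    R <- rbind(x_axis, y_axis, z_axis)              # world -> camera
    dimnames(R) <- NULL
    cams[[i]] <- camera_params(
      focal = focal, center = image_size / 2, rotation = R,
      translation = -as.numeric(R %*% pos), image_size = image_size,
      name = sprintf("cam_%02d", i))
  }
  structure(cams, class = "camera_rig")
}

camera_position <- function(cam) {
  as.numeric(-crossprod(cam$rotation, cam$translation))
}

# 3x4 projection matrix K [R | t]
projection_matrix <- function(cam) {
  K <- matrix(c(cam$focal[1], 0, 0,
                0, cam$focal[2], 0,
                cam$center[1], cam$center[2], 1), 3, 3)
  K %*% cbind(cam$rotation, cam$translation)
}

#' Project a 3D world point through a pinhole camera
#'
#' @param point Length-3 world point (meters).
#' @param cam A [camera_params()] object.
#' @return Named numeric `(u, v)` in pixels, or `NA` pair with attribute
#'   `out_of_view = TRUE` for points at or behind the image plane.
#' @export
project_point <- function(point, cam) {
  p <- as.numeric(cam$rotation %*% as.numeric(point) + cam$translation)
  if (sum(p^2) < 1e-20) stop("point coincides with the camera center")
  if (p[3] <= 1e-12) {
    out <- c(u = NA_real_, v = NA_real_)
    attr(out, "out_of_view") <- TRUE
    return(out)
  }
  u <- cam$focal[1] * p[1] / p[3] + cam$center[1]
  v <- cam$focal[2] * p[2] / p[3] + cam$center[2]
  out <- c(u = u, v = v)
  attr(out, "out_of_view") <- !(u >= 0 && u <= cam$image_size[1] &&
                                v >= 0 && v <= cam$image_size[2])
  out
}

#' Write / read a camera rig as YAML
#'
#' One document with a `cameras` list; each entry holds the intrinsic and
#' extrinsic block of a single camera.
#'
#' @param rig A `camera_rig` (list of [camera_params()]).
#' @param path File path.
#' @return `read_rig` returns a `camera_rig`.
#' @export
write_rig <- function(rig, path) {
  doc <- list(cameras = lapply(rig, function(cm) {
    list(name = cm$name %||% "cam",
         focal = as.numeric(cm$focal),
         center = as.numeric(cm$center),
         image_size = as.numeric(cm$image_size),
         rotation = lapply(seq_len(3), function(i) as.numeric(cm$rotation[i, ])),
         translation = as.numeric(cm$translation))
  }))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_rig
#' @export
read_rig <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cameras)) stop("rig file has no 'cameras' block: ", path)
  cams <- lapply(doc$cameras, function(cm) {
    camera_params(focal = cm$focal, center = cm$center,
                  rotation = do.call(rbind, cm$rotation),
                  translation = cm$translation,
                  image_size = cm$image_size, name = cm$name)
  })
  structure(cams, class = "camera_rig")
}
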
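#' 11-coefficient DLT camera
#'
#' A single view is modelled by the direct linear transformation
#' \deqn{u = (a1 X + a2 Y + a3 Z + a4) / (c1 X + c2 Y + c3 Z + 1)}
#' \deqn{v = (b1 X + b2 Y + b3 Z + b4) / (c1 X + c2 Y + c3 Z + 1)}
#' i.e. a perspective projection with the scale of the 3x4 projection matrix
#' fixed by its last entry.
#'
#' @param coef numeric vector of 11 DLT coefficients
#'   (a1..a4, b1..b4, c1..c3).
#' @param view view label, e.g. `"lateral"` or `"ventrodorsal"`.
#' @return an object of class `camera_dlt`.
#' @export
camera_dlt <- function(coef, view = "view") {
  coef <- as.numeric(coef)
  stopifnot(length(coef) == 11L, all(is.finite(coef)))
  structure(list(coef = coef, view = view), class = "camera_dlt")
}

#' @export
print.camera_dlt <- function(x, ...) {
  cat("DLT camera (", x$view, "), 11 coefficients\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

dlt_matrix <- function(camera) {
  # 3x4 projection matrix with P[3,4] = 1
  matrix(c(camera$coef[1:4], camera$coef[5:8], camera$coef[9:11], 1),
         3, 4, byrow = TRUE)
}

#' Build a camera from pinhole parameters
#'
#' Convenience constructor: a pinhole camera at `center` looking towards
#' `target`, with focal length in pixels and a principal point. The up-hint
#' fixes the image roll.
#'
#' @param center,target 3D camera position and look-at point (metres).
#' @param focal_px focal length in pixels.
#' @param principal length-2 principal point (pixels).
#' @param up approximate image "up" direction in the world.
#' @param view view label.
#' @return a `camera_dlt`.
#' @export
pinhole_camera <- function(center, target, focal_px = 2000,
                           principal = c(512, 512), up = c(0, 0, 1),
                           view = "view") {
  axis <- unit(target - center)
  if (abs(sum(axis * unit(up))) > 1 - 1e-8) {
    stop("pinhole_camera: up direction parallel to optical axis")
  }
  right <- unit(cross3(axis, up))
  down <- cross3(axis, right)  # image v grows "down"
  R <- rbind(right, down, axis)        # world -> camera
  t <- -R %*% center
  K <- matrix(c(focal_px, 0, principal[1],
                0, focal_px, principal[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  P <- K %*% cbind(R, t)
  if (abs(P[3, 4]) < 1e-12) {
    stop("pinhole_camera: degenerate geometry (camera plane through origin)")
  }
  P <- P / P[3, 4]
  camera_dlt(c(P[1, ], P[2, ], P[3, 1:3]), view = view)
}

#' Default biplanar two-view rig
#'
#' Two approximately orthogonal perspective views of the walking track: a
#' laterolateral view (optical axis along +y) and a ventrodorsal view
#' (optical axis along +z, from below), mimicking a biplanar fluoroscope.
#'
#' @param scene_center point the two optical axes converge on (metres).
#' @param distance source-to-scene distance (metres); must exceed the scene
#'   extent.
#' @param scene_extent approximate radius of the working volume (metres).
#' @param focal_px focal length in pixels.
#' @return list with elements `lateral` and `ventrodorsal`, both `camera_dlt`.
#' @export
make_two_view_rig <- function(scene_center = c(0.13, 0, 0.06),
                              distance = 1.2, scene_extent = 0.3,
                              focal_px = 2000) {
  if (distance <= scene_extent) {
    stop("make_two_view_rig: camera distance must exceed the scene extent")
  }
  lateral <- pinhole_camera(center = scene_center + c(0, -distance, 0),
                            target = scene_center, focal_px = focal_px,
                            up = c(0, 0, 1), view = "lateral")
  ventro <- pinhole_camera(center = scene_center + c(0, 0, -distance),
                           target = scene_center, focal_px = focal_px,
                           up = c(1, 0, 0), view = "ventrodorsal")
  list(lateral = lateral, ventrodorsal = ventro)
}

#' Project 3D points through a DLT camera
#'
#' Applies the linear-fractional DLT projection to a matrix of 3D points.
#' The projection is invariant under a common rescaling of all 12 entries of
#' the underlying projection matrix.
#'
#' @param camera a `camera_dlt`.
#' @param xyz numeric matrix (n x 3) or length-3 vector of 3D positions.
#' @return an n x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(camera, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  stopifnot(ncol(xyz) == 3L)
  P <- dlt_matrix(camera)
  h <- cbind(xyz, 1) %*% t(P)
  if (any(abs(h[, 3]) < 1e-9)) {
    stop("project_points: point on the camera plane (zero denominator)")
  }
  cbind(u = h[, 1] / h[, 3], v = h[, 2] / h[, 3])
}

#' Project a landmark table through a camera
#'
#' Projects a long-format 3D landmark table (columns `frame`, `landmark`,
#' `x`, `y`, `z`) into one view, producing a 2D observation table.
#'
#' @param camera a `camera_dlt`.
#' @param landmarks3d data frame with columns frame, landmark, x, y, z.
#' @return data frame with columns frame, landmark, view, u, v.
#' @export
project_landmarks <- function(camera, landmarks3d) {
  uv <- project_points(camera, as.matrix(landmarks3d[, c("x", "y", "z")]))
  data.frame(frame = landmarks3d$frame,
             landmark = landmarks3d$landmark,
             view = camera$view,
             u = uv[, 1], v = uv[, 2],
             stringsAsFactors = FALSE)
}

#' Add Gaussian pixel noise to 2D observations
#'
#' Perturbs the `u` and `v` columns with i.i.d. Gaussian noise of standard
#' deviation `sigma` pixels. `sigma = 0` returns the input unchanged.
#'
#' @param obs 2D observation data frame with columns u, v.
#' @param sigma noise standard deviation in pixels (>= 0).
#' @param seed integer seed; the perturbation is reproducible.
#' @return the observation table with perturbed u, v.
#' @export
add_pixel_noise <- function(obs, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(obs)
  with_seed(seed, {
    n <- nrow(obs)
    obs$u <- obs$u + stats::rnorm(n, 0, sigma)
    obs$v <- obs$v + stats::rnorm(n, 0, sigma)
  })
  obs
}

#' Angle between the optical axes of two cameras
#'
#' @param cam_a,cam_b `camera_dlt` objects.
#' @return angle in degrees.
#' @export
optical_axis_angle <- function(cam_a, cam_b) {
  a <- unit(cam_a$coef[9:11])
  b <- unit(cam_b$coef[9:11])
  acos(max(-1, min(1, sum(a * b)))) * 180 / pi
}

#' Serialize / restore a two-view rig as JSON
#'
#' @param rig list with `lateral` and `ventrodorsal` cameras.
#' @param path file path.
#' @return `read_rig_json` returns the rig; `write_rig_json` returns `path`
#'   invisibly.
#' @export
write_rig_json <- function(rig, path) {
  obj <- lapply(rig, function(cam) list(view = cam$view, coef = cam$coef))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rig_json
#' @export
read_rig_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(cam) camera_dlt(cam$coef, view = cam$view))
}
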
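#' Anatomical body frames
#'
#' A `body_frame` is an origin plus a right-handed orthonormal basis stored
#' column-wise in a 3x3 matrix `basis` (columns e_x, e_y, e_z), with a label.
#'
#' @param origin numeric length-3 origin in metres.
#' @param basis 3x3 matrix with basis vectors in columns.
#' @param label frame label.
#' @return an object of class `body_frame`.
#' @keywords internal
new_body_frame <- function(origin, basis, label) {
  stopifnot(length(origin) == 3L, all(dim(basis) == c(3L, 3L)))
  if (max(abs(crossprod(basis) - diag(3))) > 1e-9) {
    stop("body frame basis is not orthonormal")
  }
  if (det(basis) < 0) stop("body frame basis is not right-handed")
  structure(list(origin = as.numeric(origin), basis = basis, label = label),
            class = "body_frame")
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pelvis anatomical coordinate frame
#'
#' Builds the pelvis frame from the pelvis-cranial marker and the two hip
#' joints. The y axis points from the right hip to the left hip; an interim
#' x axis points from the right hip to the cranial marker; z is the cross
#' product of the interim x with y, and x closes the right-handed triad as
#' y x z. The origin is the centroid of the three points.
#'
#' @param p_c pelvis cranial marker (length-3, metres).
#' @param h_r,h_l right and left hip joint centres.
#' @return a `body_frame` labelled `"pelvis"`.
#' @export
pelvis_frame <- function(p_c, h_r, h_l) {
  x_int <- p_c - h_r
  e_y <- h_l - h_r
  e_z <- cross3(x_int, e_y)
  if (sqrt(sum(e_z^2)) < 1e-12 * sqrt(sum(x_int^2)) * sqrt(sum(e_y^2)) ||
      sqrt(sum(e_z^2)) == 0) {
    stop("pelvis_frame: collinear points give a degenerate frame")
  }
  e_y <- unit(e_y)
  e_z <- unit(e_z)
  e_x <- cross3(e_y, e_z)
  new_body_frame(origin = (p_c + h_r + h_l) / 3,
                 basis = cbind(e_x, e_y, e_z),
                 label = "pelvis")
}

#' Whole-leg coordinate frame
#'
#' The whole leg is the plane through the hip, the knee and the distal
#' tarsometatarsus marker; its rotation relative to the pelvis approximates
#' three-dimensional hip kinematics. The z axis points from the knee to the
#' hip; an interim x axis points from the distal tarsometatarsus marker to
#' the knee; y = z x interim-x is the plane normal (medial for the right
#' leg, lateral for the left), and x = y x z. The origin is the femur
#' midpoint.
#'
#' @param h_i,k_i,tmp_dist_i hip, knee and distal tarsometatarsus positions.
#' @param side `"left"` or `"right"` (stored in the label).
#' @return a `body_frame` labelled `"whole-leg-<side>"`.
#' @export
whole_leg_frame <- function(h_i, k_i, tmp_dist_i, side = c("left", "right")) {
  side <- match.arg(side)
  e_z <- h_i - k_i
  x_int <- k_i - tmp_dist_i
  e_y <- cross3(e_z, x_int)
  if (sqrt(sum(e_y^2)) < 1e-12 * sqrt(sum(e_z^2)) * sqrt(sum(x_int^2)) ||
      sqrt(sum(e_y^2)) == 0) {
    stop("whole_leg_frame: collinear points (fully extended leg) give a degenerate frame")
  }
  e_z <- unit(e_z)
  e_y <- unit(e_y)
  e_x <- cross3(e_y, e_z)
  new_body_frame(origin = (h_i + k_i) / 2,
                 basis = cbind(e_x, e_y, e_z),
                 label = paste0("whole-leg-", side))
}
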
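#' Elementary rotation matrices
#'
#' Right-handed rotations about the global x, y and z axes, in degrees.
#' These are the building blocks of the Cardan z-x-y decomposition used for
#' all hip and pelvis angles.
#'
#' @param deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Compose a rotation from Cardan z-x-y angles
#'
#' Returns `R = R_z(gamma) %*% R_x(alpha) %*% R_y(beta)`, i.e. intrinsic
#' rotations applied in the order z, then x, then y. This is the convention
#' under which, for the whole-leg frame expressed in the pelvis frame, the z
#' rotation is ab-adduction, the x rotation is axial (mediolateral) rotation
#' and the y rotation is flexion-extension.
#'
#' @param gamma,alpha,beta rotation angles in degrees about z, x and y.
#' @return a 3x3 rotation matrix.
#' @seealso [cardan_zxy()] for the inverse decomposition.
#' @export
compose_zxy <- function(gamma, alpha, beta) {
  rot_z(gamma) %*% rot_x(alpha) %*% rot_y(beta)
}

#' Cardan z-x-y decomposition of a rotation matrix
#'
#' Decomposes an orthonormal rotation matrix as
#' `R = R_z(gamma) %*% R_x(alpha) %*% R_y(beta)` and returns the three angles
#' in degrees on the principal branch: `gamma`, `beta` in (-180, 180],
#' `alpha` in \[-90, 90\]. Near gimbal lock (|alpha| within `lock_tol`
#' degrees of 90) a warning is emitted and the indeterminate split between
#' gamma and beta is resolved by setting beta = 0 so gamma absorbs the
#' combined rotation.
#'
#' @param R a 3x3 rotation matrix (orthonormal, det +1).
#' @param lock_tol gimbal-lock warning band in degrees (default 0.5).
#' @return named numeric vector `c(gamma, alpha, beta)` in degrees.
#' @export
cardan_zxy <- function(R, lock_tol = 0.5) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  dimnames(R) <- NULL
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
    stop("cardan_zxy: R is not a proper rotation matrix")
  }
  s_alpha <- max(-1, min(1, R[3, 2]))
  alpha <- asin(s_alpha) * 180 / pi
  if (90 - abs(alpha) < lock_tol) {
    warning("cardan_zxy: gimbal lock (|alpha| near 90 deg); gamma absorbs the indeterminacy")
    # with cos(alpha) ~ 0 only gamma -/+ beta is determined; put it all in gamma
    gamma <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    beta <- 0
  } else {
    gamma <- atan2(-R[1, 2], R[2, 2]) * 180 / pi
    beta <- atan2(-R[3, 1], R[3, 3]) * 180 / pi
  }
  c(gamma = gamma, alpha = alpha, beta = beta)
}
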
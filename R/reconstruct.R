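#' Calibration cube
#'
#' A regular grid of X-ray opaque metal spheres with known 3D positions,
#' used to calibrate each view's DLT coefficients.
#'
#' @param n_per_side spheres per cube edge (default 3, i.e. 27 spheres).
#' @param spacing grid spacing in metres.
#' @param origin position of the first sphere (metres).
#' @return data frame with columns sphere_id, x, y, z.
#' @export
make_calibration_cube <- function(n_per_side = 3, spacing = 0.05,
                                  origin = c(0, -0.05, 0)) {
  stopifnot(n_per_side >= 2)
  g <- (seq_len(n_per_side) - 1) * spacing
  grid <- expand.grid(x = g + origin[1], y = g + origin[2], z = g + origin[3])
  data.frame(sphere_id = seq_len(nrow(grid)), grid)
}

#' Calibrate one view's DLT coefficients from sphere correspondences
#'
#' Least-squares solution of the linearized projection equations (two
#' equations per sphere, eleven unknowns). At least seven non-coplanar
#' correspondences are required. 3D coordinates are centred and scaled
#' before solving, for conditioning; the result is expressed back in the
#' original coordinates.
#'
#' @param xyz n x 3 matrix of sphere positions (metres).
#' @param uv n x 2 matrix of annotated pixel positions.
#' @param view view label for the returned camera.
#' @param normalize centre/scale coordinates before solving (default TRUE).
#' @return a `camera_dlt` with attribute `"rms_error"`, the RMS reprojection
#'   error in pixels over the calibration spheres.
#' @export
calibrate_dlt <- function(xyz, uv, view = "view", normalize = TRUE) {
  xyz <- as.matrix(xyz); uv <- as.matrix(uv)
  stopifnot(ncol(xyz) == 3L, ncol(uv) == 2L, nrow(xyz) == nrow(uv))
  n <- nrow(xyz)
  if (n < 7L) {
    stop("calibrate_dlt: at least seven corresponding spheres are required (got ",
         n, ")")
  }
  if (qr(cbind(xyz, 1))$rank < 4L) {
    stop("calibrate_dlt: sphere positions are coplanar (rank-deficient calibration)")
  }
  ctr <- c(0, 0, 0); scl <- 1
  if (normalize) {
    ctr <- colMeans(xyz)
    scl <- mean(sqrt(rowSums(sweep(xyz, 2, ctr)^2)))
    if (scl < 1e-12) stop("calibrate_dlt: degenerate sphere cloud")
  }
  Xn <- sweep(xyz, 2, ctr) / scl
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    X <- Xn[i, 1]; Y <- Xn[i, 2]; Z <- Xn[i, 3]
    u <- uv[i, 1]; v <- uv[i, 2]
    A[2 * i - 1, ] <- c(X, Y, Z, 1, 0, 0, 0, 0, -u * X, -u * Y, -u * Z)
    A[2 * i, ]     <- c(0, 0, 0, 0, X, Y, Z, 1, -v * X, -v * Y, -v * Z)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  fit <- qr(A)
  if (fit$rank < 11L) {
    stop("calibrate_dlt: degenerate sphere configuration (rank ", fit$rank,
         " < 11)")
  }
  coef_n <- qr.coef(fit, b)
  # undo the 3D normalization: X_n = (X - ctr)/scl
  Pn <- matrix(c(coef_n[1:4], coef_n[5:8], coef_n[9:11], 1), 3, 4, byrow = TRUE)
  Tm <- rbind(cbind(diag(3) / scl, -ctr / scl), c(0, 0, 0, 1))
  P <- Pn %*% Tm
  P <- P / P[3, 4]
  cam <- camera_dlt(c(P[1, ], P[2, ], P[3, 1:3]), view = view)
  pred <- project_points(cam, xyz)
  attr(cam, "rms_error") <- sqrt(mean((pred - uv)^2))
  cam
}

#' Triangulate two-view observations to 3D
#'
#' For every (frame, landmark) present in both views, solves the four
#' linearized DLT equations for (X, Y, Z) by least squares and records the
#' per-view reprojection errors. Landmarks missing (absent row or NA pixel)
#' in either view stay missing: this module never interpolates.
#'
#' @param cam_d,cam_l the two calibrated cameras (e.g. ventrodorsal and
#'   lateral).
#' @param obs_d,obs_l observation tables (frame, landmark, u, v) for the
#'   matching views.
#' @param cond_warn warn when the normal-equation condition number exceeds
#'   this bound (near-parallel rays); default 1e8.
#' @return data frame with columns frame, landmark, x, y, z, err_d, err_l.
#' @export
triangulate <- function(cam_d, cam_l, obs_d, obs_l, cond_warn = 1e8) {
  key_d <- paste(obs_d$frame, obs_d$landmark, sep = "\r")
  key_l <- paste(obs_l$frame, obs_l$landmark, sep = "\r")
  ok_d <- is.finite(obs_d$u) & is.finite(obs_d$v)
  ok_l <- is.finite(obs_l$u) & is.finite(obs_l$v)
  common <- intersect(key_d[ok_d], key_l[ok_l])
  if (length(common) == 0L) stop("triangulate: no landmark observed in both views")
  i_d <- match(common, key_d)
  i_l <- match(common, key_l)
  Pd <- dlt_matrix(cam_d)
  Pl <- dlt_matrix(cam_l)
  n <- length(common)
  out <- matrix(NA_real_, n, 5)
  warned <- FALSE
  for (k in seq_len(n)) {
    ud <- obs_d$u[i_d[k]]; vd <- obs_d$v[i_d[k]]
    ul <- obs_l$u[i_l[k]]; vl <- obs_l$v[i_l[k]]
    A <- rbind(Pd[1, 1:3] - ud * Pd[3, 1:3],
               Pd[2, 1:3] - vd * Pd[3, 1:3],
               Pl[1, 1:3] - ul * Pl[3, 1:3],
               Pl[2, 1:3] - vl * Pl[3, 1:3])
    b <- c(ud * Pd[3, 4] - Pd[1, 4],
           vd * Pd[3, 4] - Pd[2, 4],
           ul * Pl[3, 4] - Pl[1, 4],
           vl * Pl[3, 4] - Pl[2, 4])
    sv <- svd(A, nu = 0, nv = 0)$d
    if (!warned && sv[3] > 0 && sv[1] / sv[3] > cond_warn) {
      warning("triangulate: near-parallel rays (condition number ",
              format(sv[1] / sv[3], digits = 3), ")")
      warned <- TRUE
    }
    xyz <- qr.coef(qr(A), b)
    ed <- sqrt(sum((project_points(cam_d, xyz) - c(ud, vd))^2))
    el <- sqrt(sum((project_points(cam_l, xyz) - c(ul, vl))^2))
    out[k, ] <- c(xyz, ed, el)
  }
  parts <- strsplit(common, "\r", fixed = TRUE)
  res <- data.frame(frame = as.integer(vapply(parts, `[`, "", 1L)),
                    landmark = vapply(parts, `[`, "", 2L),
                    x = out[, 1], y = out[, 2], z = out[, 3],
                    err_d = out[, 4], err_l = out[, 5],
                    stringsAsFactors = FALSE)
  res[order(res$frame, res$landmark), , drop = FALSE]
}

#' Per-landmark reprojection error summary
#'
#' Projects a 3D trajectory through one camera and summarizes the pixel
#' error against the observations of that view.
#'
#' @param camera a `camera_dlt`.
#' @param traj3d data frame frame, landmark, x, y, z.
#' @param obs observation table for the same view (frame, landmark, u, v).
#' @return data frame with one row per landmark: mean, median and max pixel
#'   error and the number of frames compared.
#' @export
reprojection_report <- function(camera, traj3d, obs) {
  pred <- project_landmarks(camera, traj3d)
  key_p <- paste(pred$frame, pred$landmark)
  key_o <- paste(obs$frame, obs$landmark)
  m <- match(key_p, key_o)
  keep <- !is.na(m)
  err <- sqrt((pred$u[keep] - obs$u[m[keep]])^2 +
                (pred$v[keep] - obs$v[m[keep]])^2)
  lm <- pred$landmark[keep]
  agg <- function(f) tapply(err, lm, f)
  out <- data.frame(landmark = names(agg(mean)),
                    mean_px = as.numeric(agg(mean)),
                    median_px = as.numeric(agg(stats::median)),
                    max_px = as.numeric(agg(max)),
                    n = as.integer(agg(length)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
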
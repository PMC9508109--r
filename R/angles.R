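#' Hip Cardan angles from pelvis and whole-leg frames
#'
#' Decomposes the rotation of the whole-leg frame relative to the pelvis
#' frame with the Cardan z-x-y sequence. With the left leg as reference,
#' positive x, y and z rotations are femoral inner (lateral) rotation,
#' femoral retraction (hip extension) and femoral abduction; for the right
#' leg the z and x angles are negated so both sides share the left-leg sign
#' convention. In the zero pose the pelvis and femur are orthogonal in the
#' sagittal plane, so flexion-extension is reported as beta + 90 degrees.
#'
#' @param pelvis a `body_frame` from [pelvis_frame()].
#' @param leg a `body_frame` from [whole_leg_frame()].
#' @param side `"left"` or `"right"`.
#' @return named vector `c(alpha, beta, gamma, flex_ext)` in degrees:
#'   mediolateral (x), flexion-extension (y, raw), ab-adduction (z) and the
#'   reported flexion-extension `beta + 90`.
#' @export
hip_angles <- function(pelvis, leg, side = c("left", "right")) {
  side <- match.arg(side)
  R_rel <- t(pelvis$basis) %*% leg$basis
  ang <- cardan_zxy(R_rel)
  gamma <- ang[["gamma"]]; alpha <- ang[["alpha"]]; beta <- ang[["beta"]]
  if (side == "right") {
    gamma <- -gamma
    alpha <- -alpha
  }
  c(alpha = alpha, beta = beta, gamma = gamma, flex_ext = beta + 90)
}

#' Pelvis orientation against the global frame
#'
#' Cardan z-x-y decomposition of the pelvis basis in the global frame:
#' pitch (beta, about y; negative values are retroversion, the trunk more
#' vertically oriented), roll (alpha, about x; positive tilts towards the
#' right) and yaw (gamma, about z; positive towards the left).
#'
#' @param pelvis a `body_frame`.
#' @return named vector `c(pitch, roll, yaw)` in degrees.
#' @export
pelvis_global_angles <- function(pelvis) {
  ang <- cardan_zxy(pelvis$basis)
  c(pitch = ang[["beta"]], roll = ang[["alpha"]], yaw = ang[["gamma"]])
}

#' Effective-leg length and angle
#'
#' The effective leg is the virtual segment from the hip to the tip of the
#' middle toe (Mto). Its length is the Euclidean distance; its angle is
#' measured in the global sagittal (x-z) plane from the forward horizontal,
#' below 90 degrees when the toe is cranial to the hip.
#'
#' @param hip,mto length-3 positions in metres.
#' @return named vector `c(length, alpha)` (metres, degrees).
#' @export
effective_leg <- function(hip, mto) {
  d <- mto - hip
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("effective_leg: zero-length leg")
  c(length = len, alpha = rad2deg(atan2(-d[3], d[1])))
}

#' Aperture angle between the two effective legs
#'
#' Three-dimensional angle between the hip-to-toe vectors of the two legs,
#' in \[0, 180\] degrees; symmetric under swapping the legs.
#'
#' @param hip_a,mto_a,hip_b,mto_b hip and toe positions of the two legs.
#' @return angle in degrees.
#' @export
aperture_angle <- function(hip_a, mto_a, hip_b, mto_b) {
  u <- mto_a - hip_a
  v <- mto_b - hip_b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("aperture_angle: zero-length leg")
  rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Second-order central differences (one-sided at the ends), optionally
#' preceded by a zero-phase 4th-order Butterworth low-pass filter.
#'
#' @param x numeric series (NA allowed; propagated).
#' @param fps sampling frequency in Hz.
#' @param cutoff_hz low-pass cutoff in Hz, or `NULL` to skip filtering
#'   (default 25 Hz).
#' @return numeric vector of derivatives, same length as `x`.
#' @export
differentiate <- function(x, fps, cutoff_hz = 25) {
  n <- length(x)
  if (n < 3L) stop("differentiate: series shorter than 3 samples")
  if (!is.null(cutoff_hz) && all(is.finite(x))) {
    if (cutoff_hz >= fps / 2) stop("differentiate: cutoff above Nyquist")
    bf <- signal::butter(4, cutoff_hz / (fps / 2), type = "low")
    # mean removal + odd-reflection padding suppress the filter's edge
    # transients (filtfilt starts from zero states)
    x0 <- mean(x)
    xc <- x - x0
    pad <- min(n - 1, ceiling(3 * fps / cutoff_hz))
    left <- 2 * xc[1] - xc[(pad + 1):2]
    right <- 2 * xc[n] - xc[(n - 1):(n - pad)]
    xf <- as.numeric(signal::filtfilt(bf, c(left, xc, right)))
    x <- xf[(pad + 1):(pad + n)] + x0
  }
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fps / 2
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) * fps / 2
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) * fps / 2
  d
}

#' Compute every kinematic variable from a 3D landmark trajectory
#'
#' The analysis counterpart of the generator: takes a long 3D trajectory
#' table (frame, landmark, x, y, z), builds per-frame pelvis and whole-leg
#' frames, and returns hip Cardan angles, pelvis global angles, knee /
#' intertarsal (INT) / tarsometatarsal-phalangeal (TMP) included joint
#' angles, effective-leg variables and the aperture angle. Frames where a
#' needed landmark is missing yield NA (no interpolation).
#'
#' @param traj3d data frame with columns frame, landmark, x, y, z.
#' @param fps sampling frequency (stored on the output for downstream
#'   velocity computation).
#' @return long data frame (frame, time, variable, side, value) matching
#'   the generator's ground-truth layout.
#' @export
compute_kinematics <- function(traj3d, fps = 500) {
  frames <- sort(unique(traj3d$frame))
  key <- paste(traj3d$frame, traj3d$landmark)
  pos <- function(fr, lm) {
    i <- match(paste(fr, lm), key)
    if (is.na(i)) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(traj3d[i, c("x", "y", "z")])
  }
  rows <- vector("list", length(frames))
  for (j in seq_along(frames)) {
    fr <- frames[j]
    p_c <- pos(fr, "p_c"); h_l <- pos(fr, "h_l"); h_r <- pos(fr, "h_r")
    have_pelvis <- all(is.finite(c(p_c, h_l, h_r)))
    pel <- if (have_pelvis) pelvis_frame(p_c, h_r, h_l) else NULL
    pg <- if (have_pelvis) pelvis_global_angles(pel) else
      c(pitch = NA_real_, roll = NA_real_, yaw = NA_real_)

    side_rows <- lapply(c(left = "l", right = "r"), function(sfx) {
      side <- if (sfx == "l") "left" else "right"
      h <- pos(fr, paste0("h_", sfx)); k <- pos(fr, paste0("k_", sfx))
      int <- pos(fr, paste0("int_prox_", sfx))
      tmp <- pos(fr, paste0("tmp_dist_", sfx))
      mto <- pos(fr, paste0("mto_", sfx))
      hip_ok <- all(is.finite(c(h, k, tmp))) && have_pelvis
      ha <- if (hip_ok) {
        hip_angles(pel, whole_leg_frame(h, k, tmp, side), side)
      } else c(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
               flex_ext = NA_real_)
      knee <- if (all(is.finite(c(h, k, int)))) joint_angle(h, k, int) else NA_real_
      int_a <- if (all(is.finite(c(k, int, tmp)))) joint_angle(k, int, tmp) else NA_real_
      tmp_a <- if (all(is.finite(c(int, tmp, mto)))) joint_angle(int, tmp, mto) else NA_real_
      el <- if (all(is.finite(c(h, mto)))) effective_leg(h, mto) else
        c(length = NA_real_, alpha = NA_real_)
      data.frame(
        variable = c("hip_flex", "hip_medio", "hip_abd", "knee", "int",
                     "tmp", "eff_len", "eff_alpha"),
        side = side,
        value = c(ha[["flex_ext"]], ha[["alpha"]], ha[["gamma"]], knee,
                  int_a, tmp_a, el[["length"]], el[["alpha"]]),
        stringsAsFactors = FALSE)
    })

    hl <- pos(fr, "h_l"); ml <- pos(fr, "mto_l")
    hr <- pos(fr, "h_r"); mr <- pos(fr, "mto_r")
    phi <- if (all(is.finite(c(hl, ml, hr, mr))))
      aperture_angle(hl, ml, hr, mr) else NA_real_

    body <- data.frame(
      variable = c("pelvis_pitch", "pelvis_roll", "pelvis_yaw", "aperture"),
      side = "body",
      value = c(pg[["pitch"]], pg[["roll"]], pg[["yaw"]], phi),
      stringsAsFactors = FALSE)
    rows[[j]] <- cbind(frame = fr, time = (fr - 1) / fps,
                       rbind(side_rows$left, side_rows$right, body))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
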
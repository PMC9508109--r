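#' @title Forward-kinematic gait simulation
#' @description
#' The generator turns a [gait_template] plus a [skeleton_model] into a full
#' synthetic trial: per-frame 3D positions of all 22 landmarks, a ground
#' truth table of every kinematic variable, and the stride events. The
#' prescription is hybrid: pelvis pose, hip Cardan angles, knee included
#' angle and the effective-leg sagittal angle follow the template splines
#' exactly; during stance the effective-leg length follows from the
#' ground-contact condition (toe on the substrate), during swing from the
#' template; the intertarsal and tarsometatarsal-phalangeal joints are
#' solved by planar two-link inverse kinematics inside the leg plane, so
#' every segment stays rigid to machine precision.
#'
#' Global frame: x cranial (direction of travel), y towards the animal's
#' left, z vertical up; the level substrate is z = 0.
#' @name simulate
NULL

# per-leg configuration for a trial: role, period, duty, phase offset.
# level trials drive both legs with the trailing-role curves and timing so
# the gait is strictly periodic; step trials give the leg that crosses the
# shift first the leading role.
trial_legs <- function(tpl) {
  if (tpl$condition == "level") {
    tt <- stride_timing(tpl, "trailing")
    list(
      left = list(side = "left", sign = +1, role = "trailing",
                  period = tt$period, duty = tt$duty, offset = 0),
      right = list(side = "right", sign = -1, role = "trailing",
                   period = tt$period, duty = tt$duty, offset = 0.5)
    )
  } else {
    tt <- stride_timing(tpl, "trailing")
    tl <- stride_timing(tpl, "leading")
    list(
      left = list(side = "left", sign = +1, role = "trailing",
                  period = tt$period, duty = tt$duty, offset = 0),
      right = list(side = "right", sign = -1, role = "leading",
                   period = tl$period, duty = tl$duty, offset = 0.5)
    )
  }
}

pelvis_pose <- function(tpl, t, period, shift_time = Inf) {
  phase <- t / period
  pitch <- -tpl$pelvis$retroversion +
    tpl$pelvis$pitch_amp * sin(2 * pi * 4 * phase)   # twice the step frequency
  roll <- tpl$pelvis$roll_amp * sin(2 * pi * 2 * phase)
  yaw <- tpl$pelvis$yaw_amp * sin(2 * pi * phase)
  # over a step, the pelvis height transitions to the shifted substrate
  # across one stride centred on the leading leg's touchdown
  dz <- 0
  if (is.finite(shift_time) && tpl$step_height != 0) {
    s <- min(1, max(0, (t - (shift_time - period / 2)) / period))
    dz <- tpl$step_height * s^2 * (3 - 2 * s)
  }
  origin <- c(tpl$speed * t, 0, tpl$hip_height + dz)
  list(origin = origin, R = compose_zxy(yaw, roll, pitch),
       pitch = pitch, roll = roll, yaw = yaw)
}

pelvis_local_markers <- function(skeleton) {
  d <- skeleton$lengths$pelvis_cranial_offset
  w <- skeleton$lengths$pelvis_half_width
  list(
    p_c = c(2 * d / 3, 0, 0),
    h_l = c(-d / 3, w, 0),
    h_r = c(-d / 3, -w, 0),
    p_caudal = c(-d / 3 - 0.020, 0, 0.005),
    p_left = c(0, w + 0.008, 0.010),
    p_right = c(0, -w - 0.008, 0.010)
  )
}

# in-plane direction angle theta (from "down the femur") of the hip->toe ray
# whose global sagittal angle from the forward horizontal equals alpha_deg
leg_plane_theta <- function(alpha_deg, ex, ez) {
  a <- deg2rad(alpha_deg)
  A <- ex[1] * sin(a) + ex[3] * cos(a)
  B <- ez[1] * sin(a) + ez[3] * cos(a)
  th <- atan2(B, A)
  dir <- function(th) sin(th) * ex - cos(th) * ez
  r <- function(th) {
    d <- dir(th)
    d[1] * cos(a) - d[3] * sin(a)   # projected length, > 0 for the true root
  }
  if (r(th) > 0) th else th + pi
}

# planar two-circle intersection for the distal two-link chain
# (INT -> TMP length l1, TMP -> toe length l2), in leg-plane coordinates
ik_two_link <- function(p_int, p_toe, l1, l2, bend = +1) {
  d <- p_toe - p_int
  dd <- sqrt(sum(d^2))
  if (dd > l1 + l2 + 1e-12 || dd < abs(l1 - l2) - 1e-12) {
    stop(sprintf(
      "distal chain unreachable: |INT-toe| = %.4f m outside [%.4f, %.4f]",
      dd, abs(l1 - l2), l1 + l2))
  }
  dd <- min(max(dd, abs(l1 - l2)), l1 + l2)
  a <- (l1^2 - l2^2 + dd^2) / (2 * dd)
  h2 <- l1^2 - a^2
  h <- sqrt(max(h2, 0))
  u <- d / dd
  n <- c(-u[2], u[1])              # in-plane normal
  p_int + a * u + bend * h * n
}

# minimal knee adjustment keeping the distal two-link chain solvable:
# returns the psi (tibiotarsus in-plane angle from the femur axis) nearest
# to the prescribed one whose INT position keeps |INT - toe| within reach
yield_knee <- function(psi, knee2, toe2, L) {
  dfun <- function(p) {
    i2 <- knee2 + L$tibiotarsus * c(sin(p), -cos(p))
    sqrt(sum((toe2 - i2)^2))
  }
  dmin <- abs(L$tarsometatarsus - L$toe) + 1e-4
  dmax <- L$tarsometatarsus + L$toe - 1e-4
  d0 <- dfun(psi)
  if (d0 >= dmin && d0 <= dmax) return(psi)
  target <- if (d0 < dmin) dmin else dmax
  f <- function(p) dfun(p) - target
  grid <- seq(psi - 1.2, psi + 1.2, length.out = 161)
  vals <- vapply(grid, f, 0)
  cross <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(cross)) {
    stop(sprintf(
      "distal chain unreachable: |INT-toe| = %.4f m outside [%.4f, %.4f] and no knee adjustment restores reach",
      d0, dmin, dmax))
  }
  roots <- vapply(cross, function(k) {
    stats::uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-12)$root
  }, 0)
  roots[which.min(abs(roots - psi))]
}

# full articulated pose of one leg at time t; ground gives the substrate
# height under the current stance and under the next footfall (the swing
# target), so steps are approached with a smoothly blended toe height
leg_pose <- function(skeleton, tpl, leg, pel, t, ground = c(0, 0)) {
  phase <- (t / leg$period + leg$offset) %% 1
  cur <- tpl$curves[[leg$role]]
  flex <- eval_curve(cur$hip_flex, phase)
  medio <- eval_curve(cur$hip_medio, phase)
  abd <- eval_curve(cur$hip_abd, phase)
  knee_ang <- eval_curve(cur$knee, phase)
  alpha <- eval_curve(cur$eff_alpha, phase)
  L <- skeleton$lengths

  R_rel <- compose_zxy(leg$sign * abd, leg$sign * medio, flex - 90)
  R_leg <- pel$R %*% R_rel
  ex <- R_leg[, 1]; ey <- R_leg[, 2]; ez <- R_leg[, 3]

  hip <- if (leg$side == "left") pel$markers$h_l else pel$markers$h_r
  knee <- hip - L$femur * ez

  th <- leg_plane_theta(alpha, ex, ez)
  dir3 <- sin(th) * ex - cos(th) * ez
  if (dir3[3] >= -1e-9) {
    stop("toe-height solve failed: hip->toe ray does not point downward")
  }
  in_stance <- phase < leg$duty
  z_toe <- if (in_stance) {
    ground[1]
  } else {
    # blend the substrate heights across the swing (smoothstep, C1 at the
    # ends) and add the C1 clearance bump
    s <- (phase - leg$duty) / (1 - leg$duty)
    blend <- s^2 * (3 - 2 * s)
    (1 - blend) * ground[1] + blend * ground[2] +
      tpl$swing_clearance * 16 * s^2 * (1 - s)^2
  }
  len <- (z_toe - hip[3]) / dir3[3]
  if (len <= 0) stop("effective leg length must be positive")
  toe <- hip + len * dir3

  # planar coordinates in the leg plane: p along e_x, q along e_z, hip at 0
  psi <- deg2rad(-(180 - knee_ang))
  knee2 <- c(0, -L$femur)
  toe2 <- c(len * sin(th), -len * cos(th))
  # if the prescribed knee leaves the two distal segments unable to span
  # the INT-to-toe gap, the knee yields by the smallest angle that restores
  # reach (the between-event knee values are interpolated, not pinned)
  psi <- yield_knee(psi, knee2, toe2, L)
  knee_ang <- 180 - abs(rad2deg(psi))
  int2 <- knee2 + L$tibiotarsus * c(sin(psi), -cos(psi))
  tmp2 <- ik_two_link(int2, toe2, L$tarsometatarsus, L$toe, bend = -1)

  to3 <- function(p) hip + p[1] * ex + p[2] * ez
  p_int <- to3(int2); p_tmp <- to3(tmp2)
  seg_tm <- p_tmp - p_int

  lm <- list(
    h = hip, k = knee,
    fem_mid = (hip + knee) / 2,
    tt_mid = (knee + p_int) / 2,
    int_prox = p_int,
    int_dist = p_int + 0.12 * seg_tm,
    tmp_prox = p_int + 0.45 * seg_tm,
    tmp_dist = p_tmp,
    mto = toe
  )
  names(lm) <- paste0(names(lm), if (leg$side == "left") "_l" else "_r")

  truth <- c(
    hip_flex = flex, hip_medio = medio, hip_abd = abd, knee = knee_ang,
    int = joint_angle(knee, p_int, p_tmp),
    tmp = joint_angle(p_int, p_tmp, toe),
    eff_len = len, eff_alpha = alpha
  )
  list(landmarks = lm, truth = truth, phase = phase, stance = in_stance,
       hip = hip, toe = toe)
}

#' Simulate a synthetic gait trial
#'
#' Runs the forward-kinematic generator for `n_strides` strides of the
#' trailing leg at `fps` frames per second. For step conditions the terrain
#' shift happens at the leading leg's first touchdown; contacts beginning
#' after the shift stand on the shifted substrate.
#'
#' @param skeleton a [skeleton_model].
#' @param template a [gait_template].
#' @param fps sampling frequency in Hz (default 500).
#' @param n_strides number of trailing-leg strides (>= 1).
#' @param seed integer kept for the determinism contract; the generator
#'   itself is deterministic (noise is added downstream).
#' @return an object of class `quail_trial`: list with
#'   \itemize{
#'   \item `landmarks`: long data frame (frame, time, landmark, x, y, z),
#'   \item `truth`: long data frame (frame, time, variable, side, value) of
#'     every kinematic variable in degrees / metres,
#'   \item `events`: data frame (leg, event, frame, time) of TD/TO events,
#'   \item `skeleton`, `template`, `fps`, `n_frames`, `shift_time`.
#'   }
#' @export
simulate_trial <- function(skeleton, template, fps = 500, n_strides = 1,
                           seed = 1L) {
  stopifnot(fps > 0, n_strides >= 1)
  if (template$hip_height >= max_leg_reach(skeleton)) {
    stop("simulate_trial: skeleton/template mismatch (hip height exceeds leg reach)")
  }
  legs <- trial_legs(template)
  duration <- n_strides * legs$left$period
  n_frames <- round(duration * fps)
  times <- (seq_len(n_frames) - 1) / fps
  shift_time <- if (template$condition == "level") Inf else
    (1 - legs$right$offset) %% 1 * legs$right$period   # leading leg's first TD

  pel_local <- pelvis_local_markers(skeleton)
  lm_rows <- vector("list", n_frames)
  truth_rows <- vector("list", n_frames)

  for (i in seq_len(n_frames)) {
    t <- times[i]
    pel <- pelvis_pose(template, t, legs$left$period, shift_time)
    pel$markers <- lapply(pel_local, function(p) pel$origin + as.numeric(pel$R %*% p))

    poses <- lapply(legs, function(leg) {
      # substrate heights for the current contact and the next footfall
      ph <- (t / leg$period + leg$offset) %% 1
      contact_start <- t - ph * leg$period
      g_now <- if (is.finite(shift_time) && contact_start >= shift_time - 1e-9)
        template$step_height else 0
      g_next <- if (is.finite(shift_time) &&
                    contact_start + leg$period >= shift_time - 1e-9)
        template$step_height else 0
      leg_pose(skeleton, template, leg, pel, t, ground = c(g_now, g_next))
    })

    lms <- c(pel$markers, poses$left$landmarks, poses$right$landmarks)
    lms <- lms[!duplicated(names(lms))]   # hips appear in pelvis and leg sets
    xyz <- do.call(rbind, lms)
    lm_rows[[i]] <- data.frame(frame = i, time = t,
                               landmark = rownames(xyz),
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               stringsAsFactors = FALSE)

    phi <- aperture_angle(poses$left$hip, poses$left$toe,
                          poses$right$hip, poses$right$toe)
    tv <- rbind(
      data.frame(variable = names(poses$left$truth), side = "left",
                 value = unname(poses$left$truth)),
      data.frame(variable = names(poses$right$truth), side = "right",
                 value = unname(poses$right$truth)),
      data.frame(variable = c("pelvis_pitch", "pelvis_roll", "pelvis_yaw",
                              "aperture"),
                 side = "body",
                 value = c(pel$pitch, pel$roll, pel$yaw, phi))
    )
    truth_rows[[i]] <- cbind(frame = i, time = t, tv)
  }

  events <- trial_events(legs, duration, fps)
  structure(list(
    landmarks = do.call(rbind, lm_rows),
    truth = do.call(rbind, truth_rows),
    events = events,
    skeleton = skeleton, template = template,
    fps = fps, n_frames = n_frames, n_strides = n_strides,
    shift_time = shift_time, seed = seed
  ), class = "quail_trial")
}

# exact TD/TO frames from the template clock
trial_events <- function(legs, duration, fps) {
  out <- list()
  for (leg in legs) {
    for (ev in c("TD", "TO")) {
      target <- if (ev == "TD") 0 else leg$duty
      t0 <- ((target - leg$offset) %% 1) * leg$period
      ts <- seq(t0, duration - 1e-9, by = leg$period)
      if (length(ts)) {
        out[[length(out) + 1L]] <- data.frame(
          leg = leg$side, event = ev,
          frame = round(ts * fps) + 1L, time = ts,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$leg, ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @export
print.quail_trial <- function(x, ...) {
  cat("synthetic quail trial:", x$template$condition, "|",
      x$n_frames, "frames at", x$fps, "Hz |",
      length(unique(x$landmarks$landmark)), "landmarks\n")
  invisible(x)
}

#' Calibrate the level aperture control point
#'
#' For the level template the mid-stance effective-leg angle control is the
#' one free value on the stance curve (touchdown, 15% and toe-off values
#' are fixed by the published profile). This routine solves it, by a
#' deterministic 1-D root search, so that the three-dimensional aperture
#' angle between the two effective legs at contralateral touchdown equals
#' `template$aperture_td` (53 degrees for level walking).
#'
#' @param template a level `gait_template`.
#' @param skeleton a `skeleton_model`.
#' @return the template with the calibrated control point.
#' @export
calibrate_aperture <- function(template, skeleton) {
  stopifnot(is.finite(template$aperture_td))
  cp <- template$curves$trailing$eff_alpha
  duty <- stride_timing(template, "trailing")$duty
  mid_phase <- (0.15 + duty) / 2
  idx <- which.min(abs(cp$phase - mid_phase))

  aperture_at_td <- function(mid_value) {
    tpl <- template
    tpl$curves$trailing$eff_alpha$value[idx] <- mid_value
    legs <- trial_legs(tpl)
    t_star <- (1 - legs$right$offset) * legs$right$period  # right-leg TD
    pel <- pelvis_pose(tpl, t_star, legs$left$period)
    pel$markers <- lapply(pelvis_local_markers(skeleton),
                          function(p) pel$origin + as.numeric(pel$R %*% p))
    pl <- leg_pose(skeleton, tpl, legs$left, pel, t_star)
    pr <- leg_pose(skeleton, tpl, legs$right, pel, t_star)
    aperture_angle(pl$hip, pl$toe, pr$hip, pr$toe)
  }

  f <- function(v) aperture_at_td(v) - template$aperture_td
  sol <- stats::uniroot(f, lower = 56, upper = 107, tol = 1e-10)
  template$curves$trailing$eff_alpha$value[idx] <- sol$root
  template
}
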
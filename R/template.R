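#' @title Gait templates for level and step locomotion
#' @description
#' A `gait_template` parameterizes one locomotion condition of the quail
#' step-negotiation experiments: forward speed, contact and swing durations
#' per leg role, pelvis oscillation parameters, and control-point tables for
#' every prescribed angular variable (hip flexion-extension as beta + 90,
#' whole-leg mediolateral rotation, ab-adduction, knee included angle,
#' effective-leg sagittal angle and swing length) at stride phases
#' TD, 15%, mid-stance, TO and late swing. Curves are interpolated with a
#' periodic cubic spline so level trajectories are continuous (value and
#' slope) across stride boundaries.
#'
#' The seven conditions are `level` and up/down x \{1, 2.5, 5\} cm. Level
#' control values are the published level-locomotion profiles; step
#' conditions override the event values reported for each height and
#' direction.
#' @name gait_template
NULL

#' Study conditions
#' @return character vector of the seven condition labels.
#' @export
gait_conditions <- function() {
  c("level", "up_1cm", "up_2.5cm", "up_5cm",
    "down_1cm", "down_2.5cm", "down_5cm")
}

# spatiotemporal table per condition: speed (m/s), contact & swing (s) per role
.spatiotemporal <- list(
  level       = list(speed = 0.65, contact = c(trailing = 0.23, leading = 0.22),
                     swing = c(trailing = 0.14, leading = 0.17), step_height = 0),
  up_1cm      = list(speed = 0.55, contact = c(trailing = 0.24, leading = 0.24),
                     swing = c(trailing = 0.17, leading = 0.17), step_height = 0.010),
  `up_2.5cm`  = list(speed = 0.56, contact = c(trailing = 0.30, leading = 0.33),
                     swing = c(trailing = 0.23, leading = 0.22), step_height = 0.025),
  up_5cm      = list(speed = 0.86, contact = c(trailing = 0.22, leading = 0.28),
                     swing = c(trailing = 0.20, leading = 0.17), step_height = 0.050),
  down_1cm    = list(speed = 0.51, contact = c(trailing = 0.22, leading = 0.17),
                     swing = c(trailing = 0.14, leading = 0.17), step_height = -0.010),
  `down_2.5cm` = list(speed = 0.44, contact = c(trailing = 0.29, leading = 0.21),
                     swing = c(trailing = 0.19, leading = 0.20), step_height = -0.025),
  down_5cm    = list(speed = 0.60, contact = c(trailing = 0.33, leading = 0.21),
                     swing = c(trailing = 0.14, leading = 0.20), step_height = -0.050)
)

# pelvic pitch offset magnitude (retroversion, deg) per condition
.retroversion <- c(level = 10, up_1cm = 15, `up_2.5cm` = 20, up_5cm = 28,
                   down_1cm = 10, `down_2.5cm` = 20, down_5cm = 7)

# level control-point tables as a function of the duty factor (TO phase).
# Effective-leg length at touchdown and its sagittal angles pin the hip
# height: hip_z = l_td * sin(alpha_td).
.level_controls <- function(duty, l_td = 0.13, alpha_td = 43, alpha_to = 108) {
  hip_z <- l_td * sin(deg2rad(alpha_td))
  l_to <- hip_z / sin(deg2rad(alpha_to))
  mid <- (0.15 + duty) / 2
  list(
    hip_flex = data.frame(
      phase = c(0, 0.08, 0.15, duty, 0.94, 1),
      value = c(42, 40, 41, 57, 36, 42)),
    hip_medio = data.frame(
      phase = c(0, 0.15, duty, 0.82, 1),
      value = c(-14, -6, 11, -10, -14)),
    hip_abd = data.frame(
      phase = c(0, 0.15, duty, 0.85, 1),
      value = c(36, 29, 18, 30, 36)),
    knee = data.frame(
      phase = c(0, 0.15, mid, duty, 0.80, 1),
      value = c(120, 98, 88, 60, 72, 120)),
    eff_alpha = data.frame(
      phase = c(0, 0.15, mid, duty, 0.78, 0.90, 1),
      value = c(alpha_td, 54, 81, alpha_to, 70, 38, alpha_td))
  )
}

# published event-value overrides per condition and role.
# events: td (phase 0), p15 (0.15), to (duty), p85 (duty - 0.15)
.condition_overrides <- list(
  up_1cm = list(
    trailing = list(hip_flex = c(p15 = 46), hip_medio = c(p15 = -4, to = 5),
                    hip_abd = c(p15 = 27, to = 22),
                    knee = c(p15 = 85, to = 64), eff_alpha = c(to = 89)),
    leading = list(hip_flex = c(td = 37, p85 = 62),
                   hip_medio = c(td = -7, p85 = 5), hip_abd = c(td = 25),
                   knee = c(td = 106), eff_alpha = c(td = 38))),
  `up_2.5cm` = list(
    trailing = list(hip_flex = c(p15 = 49), hip_medio = c(p15 = -2, to = 5),
                    hip_abd = c(p15 = 21, to = 14),
                    knee = c(p15 = 91, to = 73), eff_alpha = c(to = 96)),
    leading = list(hip_flex = c(td = 42, p85 = 68),
                   hip_medio = c(td = -8, p85 = 5), hip_abd = c(td = 30),
                   knee = c(td = 112), eff_alpha = c(td = 39))),
  up_5cm = list(
    trailing = list(hip_flex = c(p15 = 62), hip_medio = c(p15 = 6, to = 9),
                    hip_abd = c(p15 = 20, to = 10),
                    knee = c(p15 = 113, to = 103), eff_alpha = c(to = 100)),
    leading = list(hip_flex = c(td = 38, p85 = 66),
                   hip_medio = c(td = -9, p85 = 3), hip_abd = c(td = 25),
                   knee = c(td = 110), eff_alpha = c(td = 36))),
  down_1cm = list(
    trailing = list(hip_abd = c(p15 = 16, to = 14), eff_alpha = c(to = 104)),
    leading = list(hip_flex = c(td = 44), hip_abd = c(td = 23),
                   knee = c(td = 120), eff_alpha = c(td = 50))),
  `down_2.5cm` = list(
    trailing = list(hip_abd = c(p15 = 28, to = 17), eff_alpha = c(to = 83)),
    leading = list(hip_flex = c(td = 52), hip_medio = c(td = 3),
                   hip_abd = c(td = 34), knee = c(td = 128),
                   eff_alpha = c(td = 54))),
  down_5cm = list(
    trailing = list(hip_flex = c(p15 = 36, to = 52),
                    hip_medio = c(p15 = -11), hip_abd = c(p15 = 34, to = 16),
                    knee = c(p15 = 90, to = 48), eff_alpha = c(to = 106)),
    leading = list(hip_flex = c(td = 47), hip_medio = c(td = -1),
                   hip_abd = c(td = 34), knee = c(td = 131),
                   eff_alpha = c(td = 53)))
)

override_point <- function(df, phase, value) {
  hit <- which(abs(df$phase - phase) < 1e-9)
  if (length(hit)) {
    df$value[hit] <- value
  } else {
    df <- rbind(df, data.frame(phase = phase, value = value))
    df <- df[order(df$phase), , drop = FALSE]
  }
  # keep level/periodic consistency: value at phase 1 mirrors phase 0
  if (abs(phase) < 1e-9 && any(abs(df$phase - 1) < 1e-9)) {
    df$value[abs(df$phase - 1) < 1e-9] <- value
  }
  rownames(df) <- NULL
  df
}

apply_role_overrides <- function(controls, overrides, duty) {
  ev_phase <- c(td = 0, p15 = 0.15, to = duty, p85 = duty - 0.15)
  for (var in names(overrides)) {
    for (ev in names(overrides[[var]])) {
      controls[[var]] <- override_point(controls[[var]], ev_phase[[ev]],
                                        overrides[[var]][[ev]])
    }
  }
  controls
}

#' Construct a gait template for one study condition
#'
#' Builds the condition's spatiotemporal parameters and control-point
#' curves, starting from the level-locomotion profile and applying the
#' published event values of the requested step condition. Any field can be
#' overridden through `overrides` (named list matched against the template
#' fields, e.g. `list(speed = 0.7)` or nested
#' `list(curves = list(trailing = list(knee = data.frame(...))))`).
#'
#' For the level condition the mid-stance effective-leg control point is
#' calibrated (deterministically, via [calibrate_aperture()]) so that the
#' aperture angle between the two effective legs at contralateral touchdown
#' equals `aperture_td` (53 degrees).
#'
#' @param condition one of [gait_conditions()].
#' @param overrides named list of field overrides.
#' @param skeleton `skeleton_model` used for aperture calibration.
#' @param calibrate calibrate the level aperture control (default TRUE).
#' @return an object of class `gait_template`.
#' @export
make_gait_template <- function(condition = "level", overrides = list(),
                               skeleton = build_default_quail_skeleton(),
                               calibrate = TRUE) {
  if (!condition %in% gait_conditions()) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(gait_conditions(), collapse = ", "))
  }
  st <- .spatiotemporal[[condition]]
  duty <- st$contact / (st$contact + st$swing)
  curves <- list(
    trailing = .level_controls(duty[["trailing"]]),
    leading = .level_controls(duty[["leading"]])
  )
  ov <- .condition_overrides[[condition]]
  if (!is.null(ov)) {
    curves$trailing <- apply_role_overrides(curves$trailing, ov$trailing,
                                            duty[["trailing"]])
    curves$leading <- apply_role_overrides(curves$leading, ov$leading,
                                           duty[["leading"]])
  }
  tpl <- structure(list(
    condition = condition,
    speed = st$speed,
    contact_time = st$contact,
    swing_time = st$swing,
    step_height = st$step_height,
    hip_height = 0.13 * sin(deg2rad(43)),
    # peak toe swing clearance (m); toe height over the swing is the C1
    # bump 16 s^2 (1-s)^2 * peak, so height and vertical velocity are both
    # continuous at TD and TO
    swing_clearance = 0.017,
    pelvis = list(retroversion = unname(.retroversion[[condition]]),
                  pitch_amp = 2, roll_amp = 3, yaw_amp = 2),
    aperture_td = if (condition == "level") 53 else NA_real_,
    curves = curves
  ), class = "gait_template")
  tpl <- modify_template(tpl, overrides)
  validate_gait_template(tpl)
  if (calibrate && condition == "level" && is.finite(tpl$aperture_td)) {
    tpl <- calibrate_aperture(tpl, skeleton)
  }
  tpl
}

modify_template <- function(tpl, overrides) {
  merge_in <- function(target, src) {
    for (nm in names(src)) {
      if (is.list(src[[nm]]) && !is.data.frame(src[[nm]]) &&
          is.list(target[[nm]]) && !is.data.frame(target[[nm]])) {
        target[[nm]] <- merge_in(target[[nm]], src[[nm]])
      } else {
        target[[nm]] <- src[[nm]]
      }
    }
    target
  }
  merge_in(tpl, overrides)
}

validate_gait_template <- function(tpl) {
  if (!all(is.finite(tpl$speed)) || tpl$speed <= 0) {
    stop("gait template: speeds must be > 0")
  }
  if (any(tpl$contact_time <= 0) || any(tpl$swing_time <= 0)) {
    stop("gait template: contact and swing times must be > 0")
  }
  for (role in names(tpl$curves)) {
    for (var in names(tpl$curves[[role]])) {
      cp <- tpl$curves[[role]][[var]]
      if (any(diff(cp$phase) <= 0)) {
        stop("gait template: control phases must be strictly increasing (",
             role, "/", var, ")")
      }
      if (any(cp$phase < 0 | cp$phase > 1)) {
        stop("gait template: control phases must lie in [0, 1]")
      }
    }
  }
  invisible(tpl)
}

#' Stride period and touch-down/toe-off phases of one role
#' @param tpl a `gait_template`.
#' @param role `"trailing"` or `"leading"`.
#' @return list with `period` (s), `duty` (TO phase, TD is phase 0).
#' @export
stride_timing <- function(tpl, role = "trailing") {
  ct <- tpl$contact_time[[role]]
  sw <- tpl$swing_time[[role]]
  list(period = ct + sw, duty = ct / (ct + sw))
}

#' Evaluate a template curve at arbitrary stride phases
#'
#' Smooth interpolation of a control-point table. Variables defined over the
#' full cycle use a periodic cubic spline (requiring matching endpoint
#' values); part-cycle tables (the swing effective-leg length) use a natural
#' spline over their own phase range.
#'
#' @param cp control-point data frame (phase, value).
#' @param phase numeric vector of phases; values are taken modulo 1 for
#'   periodic curves.
#' @return numeric vector of interpolated values.
#' @export
eval_curve <- function(cp, phase) {
  full <- abs(cp$phase[1]) < 1e-9 && abs(cp$phase[nrow(cp)] - 1) < 1e-9
  if (full && abs(cp$value[1] - cp$value[nrow(cp)]) < 1e-9) {
    f <- stats::splinefun(cp$phase, cp$value, method = "periodic")
    f(phase %% 1)
  } else if (full) {
    f <- stats::splinefun(cp$phase, cp$value, method = "natural")
    f(phase %% 1)
  } else {
    f <- stats::splinefun(cp$phase, cp$value, method = "natural")
    f(pmin(pmax(phase, cp$phase[1]), cp$phase[nrow(cp)]))
  }
}

#' @export
print.gait_template <- function(x, ...) {
  cat("gait template:", x$condition,
      sprintf("| speed %.2f m/s | step %+.3f m\n", x$speed, x$step_height))
  cat(sprintf("  trailing: contact %.2f s, swing %.2f s | leading: contact %.2f s, swing %.2f s\n",
              x$contact_time[["trailing"]], x$swing_time[["trailing"]],
              x$contact_time[["leading"]], x$swing_time[["leading"]]))
  invisible(x)
}
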
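test_that("aligned frames give zero hip angles and 90 deg reported flexion", {
  pel <- pelvis_frame(c(0.02, 0, 0), c(0, -0.01, 0), c(0, 0.01, 0))
  leg <- structure(list(origin = c(0, 0.01, -0.02), basis = diag(3),
                        label = "whole-leg-left"), class = "body_frame")
  ha <- hip_angles(pel, leg, side = "left")
  expect_equal(unname(ha[c("alpha", "gamma")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(ha["flex_ext"]), 90, tolerance = 1e-12)
})

test_that("right-leg sign convention recovers the shared template values", {
  trial <- level_trial()
  angles <- compute_kinematics(trial$landmarks, fps = 500)
  for (side in c("left", "right")) {
    for (var in c("hip_flex", "hip_medio", "hip_abd")) {
      got <- angles$value[angles$variable == var & angles$side == side]
      want <- truth_series(trial, var, side)
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
})

test_that("pelvis global angles recover pitch, roll and yaw with their signs", {
  # pure retroversion: cranial axis tips up, pitch is negative
  base <- pelvis_frame(c(0.02, 0, 0), c(0, -0.01, 0), c(0, 0.01, 0))
  tip <- function(R) {
    structure(list(origin = base$origin, basis = R %*% base$basis,
                   label = "pelvis"), class = "body_frame")
  }
  pg <- pelvis_global_angles(tip(quailkin:::rot_y(-10)))
  expect_equal(unname(pg["pitch"]), -10, tolerance = 1e-9)
  pg2 <- pelvis_global_angles(tip(quailkin:::rot_z(8)))
  expect_equal(unname(pg2["yaw"]), 8, tolerance = 1e-9)
  pg3 <- pelvis_global_angles(tip(quailkin:::rot_x(5)))
  expect_equal(unname(pg3["roll"]), 5, tolerance = 1e-9)
})

test_that("full noiseless pipeline reproduces ground-truth angles to 0.1 deg", {
  sim <- noiseless_sim()
  rec <- pipeline_reconstruct(sim, observations = sim$obs)
  angles <- compute_kinematics(rec$trajectory, fps = 500)
  truth <- sim$trial$truth
  for (var in c("hip_flex", "hip_medio", "hip_abd", "knee", "int", "tmp")) {
    for (side in c("left", "right")) {
      got <- angles$value[angles$variable == var & angles$side == side]
      want <- truth$value[truth$variable == var & truth$side == side]
      expect_lt(max(abs(got - want)), 0.1)
    }
  }
  for (var in c("pelvis_pitch", "pelvis_roll", "pelvis_yaw", "aperture")) {
    got <- angles$value[angles$variable == var & angles$side == "body"]
    want <- truth$value[truth$variable == var & truth$side == "body"]
    expect_lt(max(abs(got - want)), 0.1)
  }
})

test_that("angles are invariant under global rigid motion of the landmarks", {
  trial <- level_trial()
  lm <- trial$landmarks[trial$landmarks$frame <= 10, ]
  base <- compute_kinematics(lm, fps = 500)
  R <- compose_zxy(30, 10, -20)
  shifted <- lm
  xyz <- as.matrix(lm[, c("x", "y", "z")]) %*% t(R)
  shifted$x <- xyz[, 1] + 0.5
  shifted$y <- xyz[, 2] - 0.2
  shifted$z <- xyz[, 3] + 1
  moved <- compute_kinematics(shifted, fps = 500)
  hip_vars <- c("hip_flex", "hip_medio", "hip_abd", "knee", "int", "tmp",
                "eff_len", "aperture")
  sel <- base$variable %in% hip_vars
  expect_equal(moved$value[sel], base$value[sel], tolerance = 1e-6)
})

test_that("a mirror-imaged trial yields identical curves", {
  trial <- level_trial()
  lm <- trial$landmarks[trial$landmarks$frame <= 30, ]
  base <- compute_kinematics(lm, fps = 500)
  # reflect across the sagittal plane and swap side labels
  mir <- lm
  mir$y <- -mir$y
  swap <- function(nm) {
    out <- nm
    out[grepl("_l$", nm)] <- sub("_l$", "_r", nm[grepl("_l$", nm)])
    out[grepl("_r$", nm)] <- sub("_r$", "_l", nm[grepl("_r$", nm)])
    out[nm == "p_left"] <- "p_right"
    out[nm == "p_right"] <- "p_left"
    out
  }
  mir$landmark <- swap(mir$landmark)
  mirrored <- compute_kinematics(mir, fps = 500)
  for (var in c("hip_flex", "hip_medio", "hip_abd", "knee", "eff_len")) {
    for (side in c("left", "right")) {
      other <- if (side == "left") "right" else "left"
      got <- mirrored$value[mirrored$variable == var & mirrored$side == other]
      want <- base$value[base$variable == var & base$side == side]
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("joint_angle matches hand values and rejects degenerate input", {
  expect_equal(joint_angle(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1)), 180)
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("effective leg length and angle match the closed forms", {
  el <- effective_leg(hip = c(0, 0, 0.1), mto = c(0, 0, 0))
  expect_equal(unname(el), c(0.1, 90))
  el2 <- effective_leg(hip = c(0, 0, 0.10), mto = c(0.05, 0, 0))
  expect_equal(unname(el2["length"]), sqrt(0.05^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(unname(el2["alpha"]), atan2(0.10, 0.05) * 180 / pi,
               tolerance = 1e-12)
  el3 <- effective_leg(hip = c(0, 0, 0.10), mto = c(-0.05, 0, 0))
  expect_equal(unname(el3["alpha"]), 180 - unname(el2["alpha"]),
               tolerance = 1e-12)
})

test_that("aperture angle is symmetric and matches constructions", {
  expect_equal(aperture_angle(c(0, 0.01, 0.1), c(0.05, 0.01, 0),
                              c(0, -0.01, 0.1), c(0.05, -0.01, 0)),
               0, tolerance = 1e-6)
  a <- aperture_angle(c(0, 0.01, 0.1), c(0, 0.01, 0), c(0, -0.01, 0.1),
                      c(0.1, -0.01, 0.1))
  expect_equal(a, 90, tolerance = 1e-9)
  b <- aperture_angle(c(0, -0.01, 0.1), c(0.1, -0.01, 0.1), c(0, 0.01, 0.1),
                      c(0, 0.01, 0))
  expect_equal(a, b)
})

test_that("differentiate matches closed-form derivatives", {
  expect_equal(differentiate(rep(5, 100), fps = 500), rep(0, 100))
  ramp <- seq(0, 1, length.out = 250) * 3
  d <- differentiate(ramp, fps = 500, cutoff_hz = NULL)
  k <- 3 / (249 / 500)
  expect_equal(d[2:249], rep(k, 248), tolerance = 1e-9)
  t <- seq(0, 1, by = 1 / 500)
  s <- sin(2 * pi * 5 * t)
  ds <- differentiate(s, fps = 500, cutoff_hz = 25)
  interior <- 100:400
  expect_lt(max(abs(ds[interior] - 2 * pi * 5 * cos(2 * pi * 5 * t[interior]))),
            0.01 * 2 * pi * 5)
  expect_error(differentiate(c(1, 2), fps = 500), "shorter than 3")
})
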
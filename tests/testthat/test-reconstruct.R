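test_that("DLT calibration from exact correspondences reproduces the camera", {
  rig <- make_two_view_rig()
  cube <- make_calibration_cube(2, 0.06)       # 8 spheres
  xyz <- as.matrix(cube[, c("x", "y", "z")])
  uv <- project_points(rig$lateral, xyz)
  cam <- calibrate_dlt(xyz, uv, view = "lateral")
  expect_lt(attr(cam, "rms_error"), 1e-6)
  probe <- matrix(stats::runif(30, -0.05, 0.25), ncol = 3)
  expect_equal(project_points(cam, probe), project_points(rig$lateral, probe),
               tolerance = 1e-6)
})

test_that("fewer than seven spheres or coplanar spheres are rejected", {
  rig <- make_two_view_rig()
  cube <- make_calibration_cube(2, 0.06)
  xyz <- as.matrix(cube[, c("x", "y", "z")])
  uv <- project_points(rig$lateral, xyz)
  expect_error(calibrate_dlt(xyz[1:6, ], uv[1:6, ]), "at least seven")
  flat <- xyz
  flat[, 3] <- 0.1                              # coplanar cloud
  uv_flat <- project_points(rig$lateral, flat)
  expect_error(calibrate_dlt(flat, uv_flat), "coplanar|rank")
})

test_that("calibration tolerates pixel noise at the least-squares level", {
  rig <- make_two_view_rig()
  set.seed(21)
  xyz <- matrix(stats::runif(60, -0.05, 0.25), ncol = 3)   # 20 spheres
  uv <- project_points(rig$lateral, xyz) + stats::rnorm(40, 0, 0.5)
  cam <- calibrate_dlt(xyz, uv)
  expect_lte(attr(cam, "rms_error"), 1)
  # normalized and raw solves agree on clean data
  uv_clean <- project_points(rig$lateral, xyz)
  c1 <- calibrate_dlt(xyz, uv_clean, normalize = TRUE)
  c2 <- calibrate_dlt(xyz, uv_clean, normalize = FALSE)
  expect_equal(c1$coef, c2$coef, tolerance = 1e-6)
})

test_that("noiseless project-triangulate round trip is exact", {
  rig <- make_two_view_rig()
  set.seed(13)
  pts <- matrix(stats::runif(45, -0.05, 0.25), ncol = 3)
  mk_obs <- function(cam) {
    uv <- project_points(cam, pts)
    data.frame(frame = seq_len(nrow(pts)), landmark = "p",
               u = uv[, 1], v = uv[, 2])
  }
  tr <- triangulate(rig$ventrodorsal, rig$lateral,
                    mk_obs(rig$ventrodorsal), mk_obs(rig$lateral))
  expect_lt(max(abs(as.matrix(tr[, c("x", "y", "z")]) - pts)), 1e-9)
  expect_lt(max(tr$err_d, tr$err_l), 1e-6)
})

test_that("triangulation under 0.5 px noise keeps sub-millimetre accuracy", {
  rig <- make_two_view_rig()
  set.seed(17)
  pts <- matrix(stats::runif(600, -0.05, 0.25), ncol = 3)   # 200 points
  mk_obs <- function(cam) {
    uv <- project_points(cam, pts) + stats::rnorm(2 * nrow(pts), 0, 0.5)
    data.frame(frame = seq_len(nrow(pts)), landmark = "p",
               u = uv[, 1], v = uv[, 2])
  }
  tr <- triangulate(rig$ventrodorsal, rig$lateral,
                    mk_obs(rig$ventrodorsal), mk_obs(rig$lateral))
  err <- sqrt(rowSums((as.matrix(tr[, c("x", "y", "z")]) - pts)^2))
  expect_lt(stats::median(err), 5e-4)
})

test_that("triangulation error shrinks with pixel noise", {
  rig <- make_two_view_rig()
  set.seed(19)
  pts <- matrix(stats::runif(300, -0.05, 0.25), ncol = 3)
  med_err <- sapply(c(1, 0.5, 0.1), function(sg) {
    mk_obs <- function(cam, seed) {
      uv <- project_points(cam, pts)
      set.seed(seed)
      uv <- uv + stats::rnorm(length(uv), 0, sg)
      data.frame(frame = seq_len(nrow(pts)), landmark = "p",
                 u = uv[, 1], v = uv[, 2])
    }
    tr <- triangulate(rig$ventrodorsal, rig$lateral,
                      mk_obs(rig$ventrodorsal, 1), mk_obs(rig$lateral, 2))
    stats::median(sqrt(rowSums((as.matrix(tr[, c("x", "y", "z")]) - pts)^2)))
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("landmarks missing in one view stay missing", {
  rig <- make_two_view_rig()
  pts <- matrix(stats::runif(15, 0, 0.2), ncol = 3)
  mk_obs <- function(cam) {
    uv <- project_points(cam, pts)
    data.frame(frame = seq_len(nrow(pts)), landmark = "p",
               u = uv[, 1], v = uv[, 2])
  }
  od <- mk_obs(rig$ventrodorsal)
  ol <- mk_obs(rig$lateral)
  od <- od[od$frame != 3, ]                 # absent row
  ol$u[ol$frame == 5] <- NA                 # flagged missing
  tr <- triangulate(rig$ventrodorsal, rig$lateral, od, ol)
  expect_false(any(tr$frame %in% c(3, 5)))
  expect_equal(nrow(tr), 3)
})

test_that("reprojection report matches direct error computation", {
  rig <- make_two_view_rig()
  set.seed(23)
  pts <- matrix(stats::runif(30, 0, 0.2), ncol = 3)
  traj <- data.frame(frame = 1:10, landmark = "p",
                     x = pts[, 1], y = pts[, 2], z = pts[, 3])
  uv <- project_points(rig$lateral, pts)
  obs <- data.frame(frame = 1:10, landmark = "p", u = uv[, 1], v = uv[, 2])
  rep0 <- reprojection_report(rig$lateral, traj, obs)
  expect_equal(rep0$mean_px, 0, tolerance = 1e-9)
  obs_off <- obs
  obs_off$u <- obs_off$u + 2
  rep2 <- reprojection_report(rig$lateral, traj, obs_off)
  expect_equal(rep2$mean_px, 2, tolerance = 1e-9)
  expect_equal(rep2$max_px, 2, tolerance = 1e-9)
  obs_r <- obs
  obs_r$u <- obs_r$u + stats::rnorm(10)
  obs_r$v <- obs_r$v + stats::rnorm(10)
  rep_r <- reprojection_report(rig$lateral, traj, obs_r)
  direct <- mean(sqrt((obs$u - obs_r$u)^2 + (obs$v - obs_r$v)^2))
  expect_equal(rep_r$mean_px, direct, tolerance = 1e-9)
})
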
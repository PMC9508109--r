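# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one calibrated level trial (ground truth only)
level_trial <- function() {
  fixture("level_trial", function() {
    sk <- build_default_quail_skeleton()
    tpl <- make_gait_template("level", skeleton = sk)
    simulate_trial(sk, tpl, fps = 500, n_strides = 1)
  })
}

# noiseless simulated dataset (3D truth + projections + features)
noiseless_sim <- function() {
  fixture("noiseless_sim", function() {
    cfg <- default_config()
    cfg$seed <- 7L
    cfg$simulate$pixel_noise_sd <- 0
    cfg$features$noise_sd <- 0
    pipeline_simulate(cfg)
  })
}

# the full level-gait recovery (simulate -> track -> reconstruct -> analyze)
level_recovery <- function() {
  fixture("level_recovery", function() recover_level_gait(seed = 7L))
}

# wide per-frame matrix of one ground-truth variable
truth_series <- function(trial, variable, side) {
  sel <- trial$truth$variable == variable & trial$truth$side == side
  trial$truth$value[sel][order(trial$truth$frame[sel])]
}

expect_rotation <- function(R, tol = 1e-9) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_gt(det(R), 0)
}

random_rotation <- function() {
  compose_zxy(stats::runif(1, -179, 179), stats::runif(1, -85, 85),
              stats::runif(1, -179, 179))
}
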
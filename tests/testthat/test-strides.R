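test_that("events detected from the generator toe match ground truth to 1 frame", {
  trial <- level_trial()
  sk <- build_default_quail_skeleton()
  tpl <- trial$template
  long <- simulate_trial(sk, tpl, fps = 500, n_strides = 3)
  for (lg in c("left", "right")) {
    toe <- long$landmarks[long$landmarks$landmark ==
                            paste0("mto_", substr(lg, 1, 1)), ]
    toe <- toe[order(toe$frame), ]
    det <- detect_events(data.frame(frame = toe$frame, x = toe$x, z = toe$z),
                         fps = 500)
    truth <- long$events[long$events$leg == lg, ]
    for (ev in c("TD", "TO")) {
      want <- truth$frame[truth$event == ev]
      got <- det$frame[det$event == ev]
      # interior events (sequence-boundary contacts have no detectable edge)
      interior <- want[want > 5 & want < long$n_frames - 5]
      for (w in interior) {
        expect_lte(min(abs(got - w)), 1)
      }
    }
  }
})

test_that("an airborne trajectory yields no contacts and bypass returns input", {
  toe <- data.frame(frame = 1:100, x = seq(0, 1, length.out = 100),
                    z = 0.05 + 0.01 * sin(1:100 / 5))
  expect_error(detect_events(toe, fps = 500, baseline_window = 201,
                             height_thresh = 1e-4, hysteresis = 150),
               "no contacts")
  manual <- data.frame(event = "TD", frame = 10)
  expect_identical(detect_events(toe, fps = 500, events = manual), manual)
})

test_that("level segmentation yields consecutive TD-to-TD strides per leg", {
  sk <- build_default_quail_skeleton()
  tpl <- make_gait_template("level", skeleton = sk)
  long <- simulate_trial(sk, tpl, fps = 500, n_strides = 3)
  st <- segment_strides(long$events, role = "level")
  expect_equal(sum(st$leg == "left"), 2)
  expect_equal(sum(st$leg == "right"), 2)
  expect_true(all(st$end_frame > st$start_frame))
})

test_that("step trials give one trailing and one leading stride over the shift", {
  sk <- build_default_quail_skeleton()
  tpl <- make_gait_template("up_5cm", skeleton = sk)
  long <- simulate_trial(sk, tpl, fps = 500, n_strides = 2)
  shift_frame <- round(long$shift_time * 500) + 1
  tr <- segment_strides(long$events, role = "trailing", leg = "left",
                        shift_frame = shift_frame)
  ld <- segment_strides(long$events, role = "leading", leg = "right",
                        shift_frame = shift_frame)
  expect_equal(nrow(tr), 1)
  expect_equal(nrow(ld), 1)
  expect_true(tr$start_frame <= shift_frame && tr$end_frame > shift_frame)
  expect_true(ld$start_frame <= shift_frame && ld$end_frame > shift_frame)
  expect_error(segment_strides(long$events, role = "trailing"),
               "shift_frame|unresolvable")
})

test_that("incomplete event lists drop the last stride with a warning", {
  ev <- data.frame(leg = "left", event = "TD", frame = c(10))
  expect_warning(expect_error(segment_strides(ev, role = "level"),
                              "no complete stride"),
                 "fewer than 2")
})

test_that("stride normalization is the identity on 100 samples and preserves ramps", {
  x <- stats::rnorm(100)
  expect_equal(normalize_stride(x)$values, x, tolerance = 1e-12)
  ramp <- seq(0, 99, length.out = 57)
  expect_equal(normalize_stride(ramp)$values, seq(0, 99, length.out = 100),
               tolerance = 1e-9)
  expect_length(normalize_stride(stats::rnorm(23))$values, 100L)
  # piecewise-linear min/max are preserved
  tri <- c(seq(0, 1, length.out = 34), seq(1, -1, length.out = 33),
           seq(-1, 0, length.out = 33))
  nv <- normalize_stride(tri)$values
  expect_gte(min(nv), -1)
  expect_lte(max(nv), 1)
  expect_error(normalize_stride(rep(NA_real_, 10)), "all-missing")
  expect_error(normalize_stride(1), "shorter than 2")
})

test_that("missing spans stay missing after normalization", {
  x <- stats::rnorm(50)
  x[20:30] <- NA
  nv <- normalize_stride(x)$values
  # points interpolating into the missing span are NA; ends intact
  expect_true(anyNA(nv))
  expect_false(is.na(nv[1]))
  expect_false(is.na(nv[100]))
})

test_that("mirroring flips only the x/z-rotation variables and is an involution", {
  curves <- data.frame(
    variable = c("hip_flex", "hip_medio", "hip_abd", "knee",
                 "pelvis_roll", "pelvis_yaw", "eff_alpha"),
    value = c(42, -14, 36, 120, 3, -2, 43))
  expect_identical(mirror_to_left(curves, "left"), curves)
  m <- mirror_to_left(curves, "right")
  expect_equal(m$value, c(42, 14, -36, 120, -3, 2, 43))
  expect_equal(mirror_to_left(mirror_to_left(curves, "right"), "right"), curves)
})

test_that("mean curves aggregate pointwise with per-point n", {
  a <- stats::rnorm(100)
  agg1 <- aggregate_mean_curves(list(a))
  expect_equal(agg1$mean, a)
  expect_equal(agg1$sd, rep(0, 100))
  agg2 <- aggregate_mean_curves(list(a, -a))
  expect_equal(agg2$mean, rep(0, 100), tolerance = 1e-12)
  b <- a
  b[1:10] <- NA
  agg3 <- aggregate_mean_curves(list(a, b))
  expect_equal(agg3$n[1:10], rep(1L, 10))
  expect_equal(agg3$n[11:100], rep(2L, 90))
})

test_that("event windows return event +/- 4 samples with boundary truncation", {
  curve <- structure(list(values = as.numeric(0:99),
                          event_phases = c(TD = 0, TO = 61)),
                     class = "normalized_stride")
  w <- extract_event_windows(curve, role = "trailing")
  expect_setequal(unique(w$event), c("p15", "TO"))
  w15 <- w[w$event == "p15", ]
  expect_equal(w15$phase, 11:19)       # 0-based index 15 +/- 4
  expect_equal(w15$value, 11:19)
  expect_false(any(w15$truncated))
  wl <- extract_event_windows(curve, role = "leading")
  td <- wl[wl$event == "TD", ]
  expect_equal(nrow(td), 5L)           # truncated at the curve start
  expect_true(all(td$truncated))
  const <- structure(list(values = rep(7, 100),
                          event_phases = c(TD = 10, TO = 60)),
                     class = "normalized_stride")
  wc <- extract_event_windows(const, role = "all",
                              events = c(TD = 10, TO = 60))
  expect_true(all(wc$value == 7))
  expect_error(extract_event_windows(curve, role = "all",
                                     events = c(TD = 120)),
               "outside")
})
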
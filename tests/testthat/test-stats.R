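test_that("significance codes follow the table legend exactly", {
  p <- c(0.2, 0.049, 0.009, 0.0009, 0.00009, 0.05, 0.0001)
  expect_equal(significance_code(p),
               c("", "*", "**", "***", "****", "", "***"))
})

test_that("Brown-Forsythe Levene test behaves at both extremes", {
  g <- rep(c("a", "b"), each = 10)
  x <- rep(stats::rnorm(10), 2)           # identical groups
  lv <- levene_test(x, g)
  expect_equal(lv$W, 0)
  expect_equal(lv$p, 1)
  set.seed(33)
  y <- c(stats::rnorm(50, sd = 1), stats::rnorm(50, sd = 10))
  lv2 <- levene_test(y, rep(c("a", "b"), each = 50))
  expect_lt(lv2$p, 0.01)
  expect_error(levene_test(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("Levene statistic matches the car implementation", {
  skip_if_not_installed("car")
  set.seed(44)
  x <- c(stats::rnorm(12, sd = 1), stats::rnorm(15, sd = 2),
         stats::rnorm(9, sd = 0.5))
  g <- factor(rep(c("a", "b", "c"), c(12, 15, 9)))
  mine <- levene_test(x, g)
  ref <- car::leveneTest(x, g, center = stats::median)
  expect_equal(mine$W, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("repeated-measures ANOVA flags strong within effects and null data", {
  d0 <- expand.grid(individual = paste0("s", 1:6),
                    height = c("1", "2.5", "5"),
                    direction = c("up", "down"))
  d0$value <- 1
  r0 <- rm_anova(d0)
  expect_equal(r0$F, rep(0, 3))
  expect_equal(r0$p, rep(1, 3))
  set.seed(55)
  d1 <- d0
  d1$value <- stats::rnorm(nrow(d1), sd = 0.5) +
    10 * (d1$height == "5")               # 10 SD shift with height
  r1 <- rm_anova(d1)
  expect_lt(r1$p[r1$effect == "height"], 0.0001)
  expect_lt(r1$p_gg[r1$effect == "height"], 0.0001)
  expect_gt(r1$p[r1$effect == "direction"], 0.05)
})

test_that("one-factor rm-ANOVA matches a direct sums-of-squares oracle", {
  set.seed(66)
  n <- 7; k <- 3
  d <- expand.grid(individual = paste0("s", 1:n), height = paste0("c", 1:k))
  d$value <- stats::rnorm(nrow(d)) + rep(c(0, 0.5, 1.5), each = n) +
    rep(stats::rnorm(n), k)
  res <- rm_anova(d, within = "height")
  Y <- matrix(d$value, n, k)             # subjects x conditions
  gm <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_hand <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$F, F_hand, tolerance = 1e-8)
  expect_equal(res$df1, k - 1)
  expect_equal(res$df2, (n - 1) * (k - 1))
})

test_that("unbalanced subjects are listwise-completed", {
  d <- expand.grid(individual = paste0("s", 1:5), height = c("a", "b", "c"))
  d$value <- stats::rnorm(nrow(d))
  d <- d[!(d$individual == "s5" & d$height == "c"), ]   # s5 incomplete
  res <- rm_anova(d, within = "height")
  expect_equal(res$df2, (4 - 1) * (3 - 1))              # 4 complete subjects
})

test_that("Games-Howell with two groups equals Welch's t-test", {
  set.seed(77)
  for (k in 1:20) {
    a <- stats::rnorm(sample(5:15, 1), sd = stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(5:15, 1), mean = stats::runif(1, -1, 1),
                      sd = stats::runif(1, 0.5, 3))
    gh <- posthoc(c(a, b), rep(c("a", "b"), c(length(a), length(b))),
                  homogeneous = FALSE)
    wt <- stats::t.test(a, b)
    expect_lt(abs(gh$p - wt$p.value), 1e-6)
    expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-9)
  }
})

test_that("TukeyHSD p-values match the stats implementation", {
  set.seed(88)
  x <- stats::rnorm(30)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  x[g == "c"] <- x[g == "c"] + 1
  mine <- posthoc(x, g, homogeneous = TRUE)
  ref <- stats::TukeyHSD(stats::aov(x ~ g))$g
  expect_equal(mine$p, unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("post hoc extremes: identical groups and far-separated groups", {
  x <- rep(stats::rnorm(8), 3)
  g <- rep(c("a", "b", "c"), each = 8)
  ph <- posthoc(x, g, homogeneous = TRUE)
  expect_true(all(ph$p > 0.999))
  set.seed(99)
  y <- c(stats::rnorm(16), stats::rnorm(8, mean = 100))
  ph2 <- posthoc_auto(y, g)
  far <- ph2[ph2$group1 == "c" | ph2$group2 == "c", ]
  expect_true(all(far$code == "****"))
  expect_s3_class(attr(ph2, "levene"), NA)
  expect_type(attr(ph2, "levene"), "list")
})

test_that("condition-vs-level comparisons emit one coded row per pair", {
  set.seed(111)
  mk <- function(mean, n = 10, label = "x") {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(variable = "swing_time", event = "TO", offset = -4:4,
                 value = stats::rnorm(9, mean, 0.03),
                 id = paste0(label, i))
    }))
  }
  lev <- mk(0.14, label = "l")
  # identical populations: no stars
  same <- condition_vs_level(mk(0.14, label = "c"), lev, condition = "copy")
  expect_equal(nrow(same), 1L)
  expect_gt(same$p, 0.05)
  # the published trailing swing-time shift (0.14 -> 0.20 s, SD ~ 0.03)
  up5 <- condition_vs_level(mk(0.20, label = "u"), lev, condition = "up_5cm")
  expect_true(up5$code %in% c("*", "**", "***", "****"))
  expect_true(all(c("variable", "event", "condition", "test", "p", "code")
                  %in% names(up5)))
})

test_that("the Levene gate switches the post hoc family", {
  set.seed(123)
  het <- c(stats::rnorm(30, sd = 0.1), stats::rnorm(30, sd = 5))
  g <- rep(c("a", "b"), each = 30)
  ph <- posthoc_auto(het, g)
  expect_equal(unique(ph$test), "Games-Howell")
  hom <- c(stats::rnorm(30), stats::rnorm(30, mean = 0.5))
  ph2 <- posthoc_auto(hom, g)
  expect_equal(unique(ph2$test), "TukeyHSD")
})
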
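#' Significance codes
#'
#' Maps a p-value to the star coding used throughout the results tables:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `""`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Brown-Forsythe (median-centred) Levene test
#'
#' Tests homogeneity of variances across groups by a one-way ANOVA on the
#' absolute deviations from the group medians. This is the gate used to
#' choose between TukeyHSD (homogeneous) and Games-Howell post hoc tests.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor).
#' @return list with `W` (the F statistic), `df` (numerator, denominator)
#'   and `p`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("levene_test: need >= 2 groups")
  n_i <- tabulate(groups)
  if (any(n_i < 2)) stop("levene_test: every group needs n >= 2")
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[as.integer(groups)])
  zbar_i <- tapply(z, groups, mean)
  zbar <- mean(z)
  N <- length(z)
  ss_between <- sum(n_i * (zbar_i - zbar)^2)
  ss_within <- sum((z - zbar_i[as.integer(groups)])^2)
  if (ss_within < 1e-300) {
    W <- if (ss_between < 1e-300) 0 else Inf
  } else {
    W <- (ss_between / (k - 1)) / (ss_within / (N - k))
  }
  p <- if (!is.finite(W)) 0 else stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  if (W == 0) p <- 1
  list(W = W, df = c(k - 1, N - k), p = p)
}

#' Repeated-measures ANOVA for the step conditions
#'
#' Within-subject ANOVA of a dependent variable against one or two
#' within-subject factors (step height and direction in the study design),
#' computed through `stats::aov` with an `Error(id/...)` stratum after
#' listwise completion (subjects missing any cell are dropped; cell
#' replicates are averaged). Greenhouse-Geisser sphericity-corrected
#' p-values are reported alongside the uncorrected ones.
#'
#' @param data long data frame.
#' @param dv,id names of the value and subject columns.
#' @param within character vector (length 1 or 2) of within-factor columns.
#' @return data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`, `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(data, dv = "value", id = "individual",
                     within = c("height", "direction")) {
  stopifnot(all(c(dv, id, within) %in% names(data)))
  d <- data.frame(y = data[[dv]], id = factor(data[[id]]))
  for (w in within) d[[w]] <- factor(data[[w]])
  if (any(vapply(within, function(w) nlevels(d[[w]]), 0L) < 2)) {
    stop("rm_anova: every within factor needs >= 2 levels")
  }
  # average replicates, then listwise completion
  cell <- interaction(d[within], drop = FALSE)
  agg <- stats::aggregate(d$y, by = c(list(id = d$id), d[within]), FUN = mean)
  names(agg)[ncol(agg)] <- "y"
  n_cells <- prod(vapply(within, function(w) nlevels(d[[w]]), 0L))
  counts <- table(agg$id)
  keep <- names(counts)[counts == n_cells]
  if (length(keep) < 2) stop("rm_anova: fewer than 2 complete subjects")
  agg <- agg[agg$id %in% keep, , drop = FALSE]
  agg$id <- droplevels(agg$id)

  rhs <- paste(within, collapse = "*")
  if (stats::var(agg$y) < 1e-24) {
    # degenerate: no variance anywhere, every effect is exactly null
    effects <- attr(stats::terms(stats::as.formula(paste("~", rhs))),
                    "term.labels")
    return(data.frame(effect = effects, df1 = NA_real_, df2 = NA_real_,
                      F = 0, p = 1, gg_epsilon = 1, p_gg = 1,
                      stringsAsFactors = FALSE))
  }
  form <- stats::as.formula(paste0("y ~ ", rhs, " + Error(id/(", rhs, "))"))
  fit <- stats::aov(form, data = agg)
  sm <- summary(fit)

  effects <- attr(stats::terms(stats::as.formula(paste("~", rhs))), "term.labels")
  out <- list()
  for (ef in effects) {
    row <- NULL
    for (stratum in sm) {
      tab <- stratum[[1]]
      hit <- which(trimws(rownames(tab)) == ef)
      if (length(hit)) {
        err <- which(trimws(rownames(tab)) == "Residuals")
        Fv <- tab[hit, "F value"]
        pv <- tab[hit, "Pr(>F)"]
        if (!is.finite(Fv) && tab[hit, "Sum Sq"] < 1e-300) {
          Fv <- 0; pv <- 1      # no effect variance at all
        }
        row <- data.frame(effect = ef,
                          df1 = tab[hit, "Df"], df2 = tab[err, "Df"],
                          F = Fv, p = pv,
                          stringsAsFactors = FALSE)
        break
      }
    }
    eps <- gg_epsilon(agg, ef, within)
    row$gg_epsilon <- eps
    row$p_gg <- if (is.finite(row$F) && row$F > 0) {
      stats::pf(row$F, eps * row$df1, eps * row$df2, lower.tail = FALSE)
    } else if (is.finite(row$F)) 1 else NA_real_
    out[[ef]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Greenhouse-Geisser epsilon for one within effect: eigenvalue form on the
# contrasted subject x cell covariance
gg_epsilon <- function(agg, effect, within) {
  facs <- strsplit(effect, ":", fixed = TRUE)[[1]]
  # subject x cell matrix (cells ordered by the full within design)
  cells <- interaction(agg[rev(within)], drop = FALSE, lex.order = TRUE)
  ids <- levels(agg$id)
  Y <- matrix(NA_real_, length(ids), nlevels(cells),
              dimnames = list(ids, levels(cells)))
  Y[cbind(match(agg$id, ids), match(cells, levels(cells)))] <- agg$y
  contr <- function(k) {
    cm <- stats::contr.helmert(k)
    qr.Q(qr(cm))   # orthonormal columns
  }
  M <- matrix(1, 1, 1)
  for (w in within) {
    k <- nlevels(factor(agg[[w]]))
    blk <- if (w %in% facs) t(contr(k)) else matrix(1 / k, 1, k)
    M <- kronecker(M, blk)
  }
  q <- nrow(M)
  if (q < 2) return(1)
  S <- stats::cov(Y)
  E <- M %*% S %*% t(M)
  lam <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (sum(lam^2) < 1e-300) return(1)
  min(1, max(1 / q, sum(lam)^2 / (q * sum(lam^2))))
}

#' Pairwise post hoc comparisons (TukeyHSD or Games-Howell)
#'
#' All pairwise group comparisons with studentized-range p-values. With
#' `homogeneous = TRUE` the pooled-variance TukeyHSD test is used
#' (Tukey-Kramer for unequal n); otherwise the Games-Howell test with
#' per-pair Welch degrees of freedom. The choice is normally driven by
#' [levene_test()] (see [posthoc_auto()]).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param homogeneous pooled-variance assumption flag.
#' @return data frame with one row per pair: groups, test name, mean
#'   difference, statistic `q`, df, p, significance code.
#' @export
posthoc <- function(values, groups, homogeneous = TRUE) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("posthoc: need >= 2 groups")
  n_i <- tabulate(groups)
  if (any(n_i < 2)) stop("posthoc: every group needs n >= 2")
  m_i <- tapply(values, groups, mean)
  v_i <- tapply(values, groups, stats::var)
  N <- length(values)
  mse <- sum((n_i - 1) * v_i) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  out <- list()
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    ia <- match(a, levels(groups)); ib <- match(b, levels(groups))
    diff <- m_i[ib] - m_i[ia]
    if (homogeneous) {
      se <- sqrt(mse / 2 * (1 / n_i[ia] + 1 / n_i[ib]))
      df <- N - k
      test <- "TukeyHSD"
    } else {
      s2 <- v_i[ia] / n_i[ia] + v_i[ib] / n_i[ib]
      se <- sqrt(s2 / 2)
      df <- s2^2 / (v_i[ia]^2 / (n_i[ia]^2 * (n_i[ia] - 1)) +
                      v_i[ib]^2 / (n_i[ib]^2 * (n_i[ib] - 1)))
      test <- "Games-Howell"
    }
    q <- if (se < 1e-300) {
      if (abs(diff) < 1e-300) 0 else Inf
    } else abs(diff) / se
    p <- if (!is.finite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    if (q == 0) p <- 1
    out[[c_i]] <- data.frame(group1 = a, group2 = b, test = test,
                             diff = unname(diff), q = unname(q),
                             df = unname(df), p = unname(p),
                             code = significance_code(p),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variance-homogeneity-gated post hoc tests
#'
#' Runs [levene_test()] at `alpha` and dispatches to TukeyHSD when the
#' variances are homogeneous, to Games-Howell otherwise.
#'
#' @param values,groups observations and group labels.
#' @param alpha gate level for the Levene test (default 0.05).
#' @return the [posthoc()] table with attribute `"levene"`.
#' @export
posthoc_auto <- function(values, groups, alpha = 0.05) {
  lv <- levene_test(values, groups)
  res <- posthoc(values, groups, homogeneous = lv$p >= alpha)
  attr(res, "levene") <- lv
  res
}

#' Compare one step condition against level locomotion
#'
#' For each (variable, event) pair, the nine-sample event windows
#' (event +/- 4% of the stride) of the two conditions are compared: a
#' one-way MANOVA over the window samples provides the multivariate gate,
#' and a Levene-gated post hoc test on the window means gives the reported
#' p and significance code.
#'
#' @param cond_windows,level_windows long data frames
#'   (variable, event, offset, value, id) of per-stride event windows,
#'   e.g. stacked from [extract_event_windows()].
#' @param condition label for the step condition (used in the output).
#' @param use_manova run the multivariate gate (default TRUE); set FALSE
#'   for a univariate-only comparison of window means.
#' @return data frame with one row per (variable, event): test names,
#'   statistics, p-values and significance codes.
#' @export
condition_vs_level <- function(cond_windows, level_windows,
                               condition = "step", use_manova = TRUE) {
  stopifnot(nrow(cond_windows) > 0, nrow(level_windows) > 0)
  combos <- unique(rbind(cond_windows[c("variable", "event")],
                         level_windows[c("variable", "event")]))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    vr <- combos$variable[r]; ev <- combos$event[r]
    wc <- cond_windows[cond_windows$variable == vr & cond_windows$event == ev, ]
    wl <- level_windows[level_windows$variable == vr & level_windows$event == ev, ]
    if (!nrow(wc) || !nrow(wl)) next
    mat <- function(w, grp) {
      wide <- stats::reshape(w[c("id", "offset", "value")],
                             idvar = "id", timevar = "offset",
                             direction = "wide")
      list(Y = as.matrix(wide[, -1, drop = FALSE]), grp = rep(grp, nrow(wide)))
    }
    mc <- mat(wc, condition); ml <- mat(wl, "level")
    Y <- rbind(mc$Y, ml$Y)
    grp <- factor(c(mc$grp, ml$grp))
    man_p <- NA_real_
    if (use_manova && all(stats::complete.cases(Y)) &&
        nrow(Y) > ncol(Y) + 2 && nlevels(grp) == 2) {
      keep <- apply(Y, 2, function(cl) stats::var(cl) > 1e-300)
      if (any(keep)) {
        man <- try(stats::manova(Y[, keep, drop = FALSE] ~ grp), silent = TRUE)
        if (!inherits(man, "try-error")) {
          man_p <- tryCatch(summary(man, test = "Pillai")$stats[1, "Pr(>F)"],
                            error = function(e) NA_real_)
        }
      }
    }
    means <- c(rowMeans(mc$Y, na.rm = TRUE), rowMeans(ml$Y, na.rm = TRUE))
    ph <- posthoc_auto(means, grp)
    out[[paste(vr, ev)]] <- data.frame(
      variable = vr, event = ev, condition = condition,
      test = ph$test[1], manova_p = man_p,
      diff = ph$diff[1], p = ph$p[1],
      code = significance_code(ph$p[1]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
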
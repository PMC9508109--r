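#' Linear epsilon-support-vector regression
#'
#' Solves the linear \eqn{\epsilon}-SVR problem
#' \deqn{\min_{\omega, b, \xi, \xi^*} \tfrac12 \|\omega\|^2 +
#'   C \sum_i (\xi_i + \xi_i^*)}
#' subject to \eqn{|y_i - \langle\omega, x_i\rangle - b| \le \epsilon + \xi_i},
#' \eqn{\xi_i, \xi_i^* \ge 0}, by sequential minimal optimization (SMO) on
#' the equivalent dual in \eqn{\beta_i = \alpha_i - \alpha_i^*}:
#' \deqn{\min_\beta \tfrac12 \beta^\top Q \beta - y^\top \beta +
#'   \epsilon \|\beta\|_1, \quad \sum_i \beta_i = 0,\; |\beta_i| \le C}
#' with \eqn{Q = X X^\top}. Pairs of coordinates are updated analytically
#' (the direction preserves the equality constraint; the piecewise-quadratic
#' line search handles the \eqn{\ell_1} kinks) until the maximal
#' KKT violation drops below `tol`.
#'
#' @param X numeric matrix (n x D) of training features.
#' @param y numeric vector of n scalar targets.
#' @param C box constraint (> 0); weights deviations beyond the tube.
#' @param epsilon half-width of the insensitive tube (>= 0).
#' @param tol KKT tolerance (default 1e-8).
#' @param max_iter iteration cap; non-convergence is reported with the
#'   residual violation.
#' @return list with `omega` (length D), `b`, `beta` (dual coefficients),
#'   `objective` (primal value), `kkt_violation`, `iterations`.
#' @export
train_epsilon_svr <- function(X, y, C = 1, epsilon = 0.1,
                              tol = 1e-8, max_iter = 200000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 2L) stop("train_epsilon_svr: at least 2 training samples required")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("train_epsilon_svr: non-finite inputs")
  }
  if (C <= 0 || epsilon < 0) stop("train_epsilon_svr: need C > 0 and epsilon >= 0")

  Q <- tcrossprod(X)
  beta <- numeric(n)
  g <- -y                      # gradient of the smooth part, Q beta - y

  it <- 0L
  viol <- Inf
  while (it < max_iter) {
    it <- it + 1L
    # directional derivatives with the l1 subgradient
    s_up <- ifelse(beta >= 0, epsilon, -epsilon)    # along +e_i
    s_dn <- ifelse(beta > 0, epsilon, -epsilon)     # along -e_i uses same sign set
    d_up <- g + s_up
    d_dn <- g + s_dn
    can_up <- beta < C - 1e-14
    can_dn <- beta > -C + 1e-14
    if (!any(can_up) || !any(can_dn)) break
    i <- which(can_up)[which.min(d_up[can_up])]
    viol <- max(d_dn[can_dn]) - d_up[i]  # worst improvement rate of (+e_i, -e_j)
    if (viol <= tol) break
    # second-order working-set selection: maximize the quadratic gain
    b_ij <- d_dn - d_up[i]
    q_ij <- pmax(Q[i, i] + diag(Q) - 2 * Q[, i], 1e-12)
    gain <- ifelse(can_dn & b_ij > 0, b_ij^2 / q_ij, -Inf)
    j <- which.max(gain)

    q <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
    t_max <- min(C - beta[i], beta[j] + C)
    # candidate steps: kink points, box end, and the per-piece minimizers
    cand <- c(t_max)
    for (bp in c(-beta[i], beta[j])) {
      if (bp > 0 && bp < t_max) cand <- c(cand, bp)
    }
    if (q > 1e-300) {
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
        tt <- -(g[i] - g[j] + epsilon * s1 + epsilon * s2) / q
        if (tt > 0 && tt < t_max) cand <- c(cand, tt)
      }
    }
    delta <- function(t) {
      0.5 * q * t^2 + (g[i] - g[j]) * t +
        epsilon * (abs(beta[i] + t) - abs(beta[i])) +
        epsilon * (abs(beta[j] - t) - abs(beta[j]))
    }
    dvals <- vapply(cand, delta, 0)
    best <- cand[which.min(dvals)]
    if (min(dvals) >= -1e-300 || best <= 0) break   # numerically stalled
    beta[i] <- beta[i] + best
    beta[j] <- beta[j] - best
    g <- g + best * (Q[, i] - Q[, j])
  }
  if (it >= max_iter && viol > tol) {
    warning(sprintf(
      "train_epsilon_svr: SMO stopped at max_iter with KKT violation %.3g", viol))
  }

  omega <- as.numeric(crossprod(X, beta))
  b <- svr_intercept(beta, g, C, epsilon)
  fitted <- as.numeric(X %*% omega) + b
  slack <- pmax(0, abs(y - fitted) - epsilon)
  list(omega = omega, b = b, beta = beta,
       objective = 0.5 * sum(omega^2) + C * sum(slack),
       kkt_violation = viol, iterations = it)
}

# intercept from the KKT conditions: free SVs pin b exactly, otherwise the
# feasible interval from the bound/inactive points is bisected
svr_intercept <- function(beta, g, C, epsilon) {
  free <- abs(beta) > 1e-10 & abs(beta) < C - 1e-10
  if (any(free)) {
    return(mean(-g[free] - epsilon * sign(beta[free])))
  }
  lo <- -Inf; hi <- Inf
  for (i in seq_along(beta)) {
    if (abs(beta[i]) <= 1e-10) {            # inside the tube
      lo <- max(lo, -g[i] - epsilon)
      hi <- min(hi, -g[i] + epsilon)
    } else if (beta[i] >= C - 1e-10) {      # at the upper bound
      hi <- min(hi, -g[i] - epsilon)
    } else {                                # at the lower bound
      lo <- max(lo, -g[i] + epsilon)
    }
  }
  if (!is.finite(lo) && !is.finite(hi)) return(0)
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' Predict from a fitted linear SVR
#'
#' @param fit result of [train_epsilon_svr()].
#' @param X matrix of feature rows.
#' @return numeric vector of predictions.
#' @export
predict_svr <- function(fit, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(fit$omega))
  as.numeric(X %*% fit$omega) + fit$b
}
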
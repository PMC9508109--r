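#' Synthesize per-frame multi-view feature vectors
#'
#' Stand-in for a learned image representation: for every frame the 2D
#' landmark coordinates of both views are concatenated, standardized, and
#' pushed through a fixed random affine map that is injective on the signal
#' subspace, so a linear regressor can recover landmark positions exactly
#' in the noiseless limit. Optional distractor channels (bounded nonlinear
#' functions of the signal) and i.i.d. Gaussian channel noise emulate the
#' nuisance structure of real features.
#'
#' @param obs_d,obs_l observation tables of the two views (frame, landmark,
#'   u, v), complete for every frame.
#' @param D feature dimension; must be at least twice the number of
#'   landmark coordinates (2 views x 2 coords x landmarks).
#' @param noise_sd Gaussian noise SD per channel, in units of the (unit)
#'   standardized signal SD; default 0.01 (1%).
#' @param n_distractors number of nonlinear distractor channels (default 8).
#' @param seed integer seed fixing the random map and the noise.
#' @return list with `features` (L x D matrix, rows ordered by frame),
#'   `frames` (frame indices) and `meta`.
#' @export
synthesize_features <- function(obs_d, obs_l, D = 192, noise_sd = 0.01,
                                n_distractors = 8, seed = 1L) {
  S <- observation_signal(obs_d, obs_l)
  p <- ncol(S)
  if (D < 2 * p) {
    stop("synthesize_features: D must be >= ", 2 * p,
         " (twice the number of landmark coordinates)")
  }
  stopifnot(noise_sd >= 0, n_distractors >= 0, D - n_distractors >= p)
  ctr <- colMeans(S)
  scl <- apply(S, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(S, 2, ctr), 2, scl, "/")
  L <- nrow(Z)
  feats <- with_seed(seed, {
    n_affine <- D - n_distractors
    A <- matrix(stats::rnorm(p * n_affine), p, n_affine) / sqrt(p)
    offs <- stats::rnorm(n_affine)
    Fa <- Z %*% A + matrix(offs, L, n_affine, byrow = TRUE)
    Fd <- NULL
    if (n_distractors > 0) {
      W <- matrix(stats::rnorm(p * n_distractors), p, n_distractors) / sqrt(p)
      Fd <- sin(Z %*% W)
    }
    out <- cbind(Fa, Fd)
    if (noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), 0, noise_sd),
                          nrow(out), ncol(out))
    }
    out
  })
  list(features = feats,
       frames = sort(unique(obs_d$frame)),
       meta = list(D = D, noise_sd = noise_sd,
                   n_distractors = n_distractors, seed = seed,
                   signal_dim = p))
}

# frame-ordered signal matrix: (u, v) of every landmark in both views
observation_signal <- function(obs_d, obs_l) {
  frames <- sort(unique(obs_d$frame))
  lms <- sort(unique(obs_d$landmark))
  if (!identical(frames, sort(unique(obs_l$frame)))) {
    stop("observation tables cover different frames")
  }
  block <- function(obs, view_tag) {
    m <- matrix(NA_real_, length(frames), 2 * length(lms))
    key <- paste(obs$frame, obs$landmark)
    for (k in seq_along(lms)) {
      idx <- match(paste(frames, lms[k]), key)
      m[, 2 * k - 1] <- obs$u[idx]
      m[, 2 * k] <- obs$v[idx]
    }
    colnames(m) <- paste0(view_tag, ".", rep(lms, each = 2), c(".u", ".v"))
    m
  }
  S <- cbind(block(obs_d, "d"), block(obs_l, "l"))
  if (anyNA(S)) stop("observation tables are incomplete (missing landmark rows)")
  S
}
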
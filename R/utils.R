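#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package functions are deterministic without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Included angle at a joint
#'
#' The three-dimensional included angle at `joint` between the rays towards
#' `proximal` and `distal`, in degrees, in (0, 180). Flexion decreases the
#' value.
#'
#' @param proximal,joint,distal length-3 positions (metres).
#' @return angle in degrees.
#' @export
joint_angle <- function(proximal, joint, distal) {
  a <- proximal - joint
  b <- distal - joint
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("joint_angle: zero-length segment")
  rad2deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}
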
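#' Articulated quail hindlimb skeleton
#'
#' Defines the bilateral landmark catalog (22 named points) and the segment
#' lengths of the articulated hindlimb chain
#' hip -> knee -> intertarsal -> distal tarsometatarsus -> middle-toe tip.
#' Beyond the kinematically necessary points, filler markers are rigidly
#' attached to existing segments to reach the full catalog of 22.
#'
#' @param lengths named list of segment lengths in metres:
#'   `pelvis_half_width`, `pelvis_cranial_offset`, `femur`, `tibiotarsus`,
#'   `tarsometatarsus`, `toe`. Lengths apply to both sides (bilateral
#'   symmetry).
#' @return an object of class `skeleton_model` with fields `lengths` and
#'   `catalog` (character vector of 22 unique landmark names).
#' @export
skeleton_model <- function(lengths) {
  required <- c("pelvis_half_width", "pelvis_cranial_offset", "femur",
                "tibiotarsus", "tarsometatarsus", "toe")
  missing <- setdiff(required, names(lengths))
  if (length(missing)) {
    stop("skeleton_model: missing segment lengths: ",
         paste(missing, collapse = ", "))
  }
  lv <- unlist(lengths[required])
  if (any(!is.finite(lv)) || any(lv <= 0)) {
    stop("skeleton_model: all segment lengths must be finite and > 0")
  }
  catalog <- c(
    "p_c", "p_caudal", "p_left", "p_right",          # pelvis
    paste0(c("h", "fem_mid", "k", "tt_mid", "int_prox", "int_dist",
             "tmp_prox", "tmp_dist", "mto"), "_l"),  # left chain
    paste0(c("h", "fem_mid", "k", "tt_mid", "int_prox", "int_dist",
             "tmp_prox", "tmp_dist", "mto"), "_r")   # right chain
  )
  stopifnot(length(catalog) == 22L, !anyDuplicated(catalog))
  structure(list(lengths = as.list(lv), catalog = catalog),
            class = "skeleton_model")
}

#' Default quail skeleton
#'
#' Segment lengths representative of an adult common quail, chosen so the
#' stance effective-leg length (hip to middle-toe tip) spans roughly
#' 0.09-0.15 m and the fully extended chain reaches at least 0.15 m.
#'
#' @return a `skeleton_model`.
#' @examples
#' sk <- build_default_quail_skeleton()
#' length(sk$catalog)            # 22 landmarks
#' max_leg_reach(sk)             # > 0.15 m
#' @export
build_default_quail_skeleton <- function() {
  skeleton_model(list(
    pelvis_half_width = 0.020,
    pelvis_cranial_offset = 0.035,
    femur = 0.050,
    tibiotarsus = 0.073,
    tarsometatarsus = 0.046,
    toe = 0.043
  ))
}

#' Maximum hip-to-toe reach of the straightened leg
#'
#' @param skeleton a `skeleton_model`.
#' @return the sum of the distal-chain segment lengths in metres.
#' @export
max_leg_reach <- function(skeleton) {
  with(skeleton$lengths, femur + tibiotarsus + tarsometatarsus + toe)
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("quail hindlimb skeleton:", length(x$catalog), "landmarks\n")
  cat(sprintf("  %-22s %.3f m\n", names(x$lengths), unlist(x$lengths)), sep = "")
  invisible(x)
}
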
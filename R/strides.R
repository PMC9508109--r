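#' Detect touch-down and toe-off events from a toe trajectory
#'
#' Contact is declared while the toe height stays within `height_thresh` of
#' a local ground baseline (rolling minimum over `baseline_window` frames,
#' which follows terrain shifts); runs shorter than `hysteresis` frames are
#' discarded. TD is the first frame of a contact run, TO the first frame
#' after it. An optional forward-speed gate additionally requires the toe
#' to be (near) stationary. Manually digitized event tables always take
#' precedence: when `events` is supplied it is returned unchanged.
#'
#' @param toe data frame (frame, x, z) of one leg's toe trajectory, metres.
#' @param fps sampling frequency in Hz.
#' @param height_thresh contact band above the local ground in metres
#'   (default 1e-5, matched to the exact substrate contact of the generator;
#'   real, noisier data should use manually digitized event tables).
#' @param hysteresis minimum run length in frames (default 10).
#' @param baseline_window rolling-minimum window in frames (default 51).
#' @param speed_gate optional maximum absolute toe forward speed during
#'   contact, m/s (`NULL` = disabled, the default: a rolling contact slides
#'   the toe slowly forward during stance).
#' @param events optional pre-digitized event table, returned as-is.
#' @return data frame (event, frame) with events `"TD"`/`"TO"`.
#' @export
detect_events <- function(toe, fps, height_thresh = 1e-5, hysteresis = 10,
                          baseline_window = 51, speed_gate = NULL,
                          events = NULL) {
  if (!is.null(events)) return(events)
  n <- nrow(toe)
  stopifnot(n > 2)
  half <- baseline_window %/% 2
  base <- vapply(seq_len(n), function(i) {
    min(toe$z[max(1, i - half):min(n, i + half)])
  }, 0)
  contact <- toe$z - base < height_thresh
  if (!is.null(speed_gate)) {
    vx <- abs(differentiate(toe$x, fps, cutoff_hz = NULL))
    contact <- contact & vx < speed_gate
  }
  # enforce hysteresis: drop runs shorter than the minimum length
  r <- rle(contact)
  short <- r$lengths < hysteresis
  if (any(short & r$values)) r$values[short & r$values] <- FALSE
  contact <- inverse.rle(r)
  if (!any(contact)) stop("detect_events: no contacts found")
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  td <- starts[r$values]
  to <- ends[r$values] + 1L
  to <- to[to <= n]
  ev <- rbind(
    if (length(td)) data.frame(event = "TD", frame = toe$frame[td]),
    if (length(to)) data.frame(event = "TO", frame = toe$frame[to]))
  ev[order(ev$frame), , drop = FALSE]
}

#' Segment a trial into strides
#'
#' Stride windows follow the study's event definitions: on level trials a
#' stride runs from one touch-down to the next of the same leg; around a
#' terrain shift the trailing limb's stride runs from its TD on the level
#' plate to its TD on the shifted plate, and the leading limb's stride from
#' TO on the level plate to TO on the shifted plate.
#'
#' @param events event table (leg, event, frame) as returned by the
#'   generator or [detect_events()] (with a `leg` column added).
#' @param role `"level"`, `"trailing"` or `"leading"`.
#' @param leg which leg to segment (required for step roles; for
#'   `"level"`, all legs present are segmented).
#' @param shift_frame frame of the terrain shift (required for step roles).
#' @return data frame (leg, role, start_frame, end_frame), one row per
#'   stride.
#' @export
segment_strides <- function(events, role = c("level", "trailing", "leading"),
                            leg = NULL, shift_frame = NULL) {
  role <- match.arg(role)
  if (role == "level") {
    out <- list()
    for (lg in unique(events$leg)) {
      td <- sort(events$frame[events$leg == lg & events$event == "TD"])
      if (length(td) < 2) {
        warning("segment_strides: leg '", lg, "' has fewer than 2 touch-downs; ",
                "no complete stride")
        next
      }
      out[[lg]] <- data.frame(leg = lg, role = "level",
                              start_frame = utils::head(td, -1),
                              end_frame = td[-1], stringsAsFactors = FALSE)
    }
    if (!length(out)) stop("segment_strides: no complete stride in any leg")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }
  if (is.null(leg) || is.null(shift_frame)) {
    stop("segment_strides: step roles need `leg` and `shift_frame` ",
         "(no terrain shift makes the role unresolvable)")
  }
  ev_type <- if (role == "trailing") "TD" else "TO"
  fr <- sort(events$frame[events$leg == leg & events$event == ev_type])
  before <- fr[fr <= shift_frame]
  after <- fr[fr > shift_frame]
  if (!length(before) || !length(after)) {
    stop("segment_strides: no ", ev_type, " pair spanning the shift for leg '",
         leg, "'")
  }
  data.frame(leg = leg, role = role,
             start_frame = max(before), end_frame = min(after),
             stringsAsFactors = FALSE)
}

#' Time-normalize a stride to 100 samples
#'
#' Linear interpolation of a per-frame series onto 100 equally spaced
#' phase points over the stride window; the window endpoints are preserved
#' exactly. Missing spans stay missing: a target point is NA when either
#' flanking source sample is NA.
#'
#' @param values numeric series over the stride window (>= 2 samples).
#' @param event_frames optional named vector of event frame positions
#'   (1-based, within the window) recorded as phases (0-100) on the output.
#' @return object of class `normalized_stride`: list with `values`
#'   (length 100) and `event_phases`.
#' @export
normalize_stride <- function(values, event_frames = NULL) {
  n <- length(values)
  if (n < 2L) stop("normalize_stride: window shorter than 2 samples")
  if (all(is.na(values))) stop("normalize_stride: all-missing input")
  pos <- seq(1, n, length.out = 100)
  lo <- floor(pos); hi <- ceiling(pos); wt <- pos - lo
  out <- (1 - wt) * values[lo] + wt * values[hi]
  exact <- wt < 1e-12
  out[exact] <- values[lo[exact]]   # endpoints (and exact hits) preserved
  phases <- NULL
  if (!is.null(event_frames)) {
    phases <- (event_frames - 1) / (n - 1) * 100
    if (any(phases < 0 | phases > 100)) {
      stop("normalize_stride: event outside the stride window")
    }
  }
  structure(list(values = as.numeric(out), event_phases = phases),
            class = "normalized_stride")
}

#' Mirror right-side curves to the left-leg convention
#'
#' To pool strides the data are transformed so the trailing limb is always
#' the left leg: for right-side trials the x- and z-rotation variables
#' (whole-leg mediolateral rotation and ab-adduction, pelvic roll and yaw)
#' are negated; flexion-extension, joint and effective-leg variables are
#' unchanged. Mirroring a left-side trial is the identity, and mirroring
#' twice restores the input.
#'
#' @param curves long data frame with `variable` and `value` columns.
#' @param side `"left"` or `"right"`.
#' @return the curves with the sign convention applied.
#' @export
mirror_to_left <- function(curves, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") return(curves)
  flip <- curves$variable %in% c("hip_medio", "hip_abd",
                                 "pelvis_roll", "pelvis_yaw")
  curves$value[flip] <- -curves$value[flip]
  curves
}

#' Pointwise mean and SD of normalized strides
#'
#' Missing values are ignored pointwise and the per-point sample size is
#' reported, so sparsely observed stride portions (e.g. hip landmarks
#' missing near the stride boundaries) are visible in the output.
#'
#' @param strides list of `normalized_stride` objects (or plain length-100
#'   numeric vectors).
#' @return data frame (phase 0-99, mean, sd, n).
#' @export
aggregate_mean_curves <- function(strides) {
  stopifnot(length(strides) >= 1)
  vals <- vapply(strides, function(s) {
    v <- if (inherits(s, "normalized_stride")) s$values else as.numeric(s)
    stopifnot(length(v) == 100L)
    v
  }, numeric(100))
  vals <- matrix(vals, nrow = 100)
  n <- rowSums(!is.na(vals))
  mean_v <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  sd_v <- apply(vals, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::sd(r) else if (length(r) == 1) 0 else NA_real_
  })
  data.frame(phase = 0:99, mean = mean_v, sd = sd_v, n = n)
}

#' Extract event-centred analysis windows
#'
#' For each analysis event the value at the event phase plus the four
#' preceding and four following points of the 100-sample stride
#' (event +/- 4% of the stride) are returned. Trailing-limb strides are
#' analyzed at early stance (15%) and TO; leading-limb strides at TD and
#' late stance (85%). Windows truncated by the curve boundary are flagged.
#' Phase indexing is 0-based over 0..99, so "15%" is index 15.
#'
#' @param stride a `normalized_stride` (with `event_phases` holding at
#'   least `TD` and `TO`) or a length-100 vector plus explicit `events`.
#' @param role `"trailing"` or `"leading"` (selects the event set), or
#'   `"all"` to extract every event in `events`.
#' @param events named vector of event phases in percent (0-100);
#'   defaults to the stride's recorded phases plus fixed 15% / 85% marks.
#' @param half_width window half width in samples (default 4).
#' @return data frame (event, offset, phase, value, truncated).
#' @export
extract_event_windows <- function(stride, role = c("trailing", "leading", "all"),
                                  events = NULL, half_width = 4) {
  role <- match.arg(role)
  values <- if (inherits(stride, "normalized_stride")) stride$values else
    as.numeric(stride)
  stopifnot(length(values) == 100L)
  if (is.null(events)) {
    base <- if (inherits(stride, "normalized_stride")) stride$event_phases else
      c(TD = 0, TO = NA)
    events <- c(base, p15 = 15, p85 = 85)
  }
  wanted <- switch(role,
                   trailing = c("p15", "TO"),
                   leading = c("TD", "p85"),
                   all = names(events))
  out <- list()
  for (ev in wanted) {
    ph <- events[[ev]]
    if (is.null(ph) || is.na(ph)) stop("extract_event_windows: unknown phase for event ", ev)
    if (ph < 0 || ph > 100) stop("extract_event_windows: event outside [0, 100]")
    centre <- round(ph)
    idx <- (centre - half_width):(centre + half_width)
    ok <- idx >= 0 & idx <= 99
    out[[ev]] <- data.frame(event = ev, offset = idx[ok] - centre,
                            phase = idx[ok],
                            value = values[idx[ok] + 1L],
                            truncated = !all(ok),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
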
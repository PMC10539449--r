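#' Kinematic analysis of motion streams
#'
#' Derives the study's hand-movement outcomes from raw 90 Hz
#' headset/controller streams: interception (racquet-ball contact),
#' peak foreswing velocity toward the target, and transverse-plane range of
#' motion. Positions are first smoothed with a dual-pass, zero-phase
#' Butterworth filter at 10 Hz; the foreswing runs from the first forward
#' racquet motion to ball contact (or, on misses, the last sample at which
#' the ball's depth still exceeded the racquet's).
#'
#' @name kinematics_pipeline
NULL

#' Dual-pass zero-phase Butterworth smoothing of a motion stream
#'
#' Second-order low-pass applied forward and backward (fourth-order
#' effective response, zero phase lag) to each positional coordinate.
#' Short gaps (`<= 2` samples of NA) are linearly interpolated first; longer
#' gaps raise an error so the caller can flag the trial.
#'
#' @param stream motion tibble with columns `t` plus coordinates.
#' @param cutoff Hz (default 10).
#' @param cols columns to filter (default all position columns present).
#' @return the stream with filtered columns.
#' @export
smooth_motion <- function(stream, cutoff = 10,
                          cols = intersect(c("hx", "hy", "hz", "cx", "cy", "cz"),
                                           names(stream))) {
  dt <- diff(stream$t)
  if (any(abs(dt - dt[1]) > 1e-6)) stop("smooth_motion requires uniform sampling")
  fs <- 1 / dt[1]
  if (nrow(stream) < 12) stop("stream too short for the filter warm-up")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  for (cl in cols) {
    y <- stream[[cl]]
    y <- fill_short_gaps(y, max_gap = 2)
    if (anyNA(y)) stop("gap longer than 2 samples in column ", cl)
    stream[[cl]] <- filtfilt_refl(bf, y)
  }
  stream
}

# Linear interpolation of NA runs no longer than max_gap samples.
fill_short_gaps <- function(y, max_gap = 2) {
  if (!anyNA(y)) return(y)
  r <- rle(is.na(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values & r$lengths <= max_gap)) {
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    if (i0 < 1 || i1 > length(y)) next
    y[starts[k]:ends[k]] <- approx(c(i0, i1), y[c(i0, i1)],
                                   xout = starts[k]:ends[k])$y
  }
  y
}

#' Detect racquet-ball contact
#'
#' Contact is the first time at which the ball centre lies within the
#' racquet's oriented box inflated by the ball radius (closed boundary).
#' The controller pose is linearly interpolated onto a 1 kHz grid and the
#' ball evaluated analytically, so brief overlaps between stream samples
#' are not missed.
#'
#' @param hand motion tibble (columns `t`, `cx`, `cy`, `cz`, and optionally
#'   `cyaw`, `cpitch` for the racquet orientation).
#' @param ball a `"ball_trajectory"`.
#' @param racquet_halfext half-extents of the racquet box in metres.
#' @param ball_radius metres.
#' @return list with `intercepted` (logical) and `t_contact` (s or NA).
#' @export
detect_interception <- function(hand, ball,
                                racquet_halfext = RACQUET_HALFEXT,
                                ball_radius = BALL_RADIUS) {
  t0 <- max(min(hand$t), ball$t_launch)
  t1 <- min(max(hand$t), ball$t_end)
  tt <- seq(t0, t1, by = 0.001)
  cx <- approx(hand$t, hand$cx, tt)$y
  cy <- approx(hand$t, hand$cy, tt)$y
  cz <- approx(hand$t, hand$cz, tt)$y
  bp <- ball_state_at(ball, tt)$position
  rel <- bp - cbind(cx, cy, cz)
  if (!is.null(hand$cyaw) && (any(hand$cyaw != 0) || any(hand$cpitch != 0))) {
    cyaw <- approx(hand$t, hand$cyaw, tt)$y
    cpitch <- approx(hand$t, hand$cpitch, tt)$y
    rel <- t(vapply(seq_along(tt), function(i) {
      ax <- head_axes(cyaw[i], cpitch[i])
      c(sum(rel[i, ] * ax$right), sum(rel[i, ] * ax$up),
        sum(rel[i, ] * ax$forward))
    }, numeric(3)))
  }
  hit <- in_racquet_box(rel, racquet_halfext, ball_radius)
  if (any(hit)) list(intercepted = TRUE, t_contact = tt[which(hit)[1]])
  else list(intercepted = FALSE, t_contact = NA_real_)
}

#' Detect the foreswing window
#'
#' Onset is the first sample of the last pre-offset run in which forward
#' (+z) controller velocity exceeds `v_thresh` for at least `k` consecutive
#' samples; offset is the contact time when the trial was intercepted,
#' otherwise the final sample at which the ball's depth position exceeded
#' the racquet's.
#'
#' @param hand smoothed motion tibble.
#' @param ball a `"ball_trajectory"`.
#' @param t_contact contact time in seconds, or NA for a miss.
#' @param v_thresh forward-velocity threshold, m/s (default 0.2).
#' @param k consecutive samples above threshold required (default 3,
#'   about 33 ms at 90 Hz).
#' @return list with `t_onset`, `t_offset`, `offset_kind` (`"contact"` or
#'   `"ball_passed"`) and `flagged` (TRUE when no forward motion was found).
#' @export
detect_foreswing <- function(hand, ball, t_contact = NA_real_,
                             v_thresh = 0.2, k = 3) {
  vz <- central_diff(hand$cz, hand$t)
  if (!is.na(t_contact)) {
    t_offset <- t_contact
    offset_kind <- "contact"
  } else {
    bz <- ball_state_at(ball, pmin(hand$t, ball$t_end))$position[, 3]
    ahead <- bz > hand$cz & hand$t <= ball$t_end
    if (!any(ahead)) {
      return(list(t_onset = NA_real_, t_offset = NA_real_,
                  offset_kind = "ball_passed", flagged = TRUE))
    }
    t_offset <- hand$t[max(which(ahead))]
    offset_kind <- "ball_passed"
  }
  pre <- hand$t <= t_offset
  fast <- vz > v_thresh & pre
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= k)
  if (!length(ok)) {
    return(list(t_onset = NA_real_, t_offset = t_offset,
                offset_kind = offset_kind, flagged = TRUE))
  }
  # the threshold crossing lags the true movement start; walk back to the
  # beginning of the forward-motion ramp (bounded lookback)
  i <- starts[max(ok)]
  while (i > 1 && vz[i - 1] > 0.05 * v_thresh &&
         hand$t[starts[max(ok)]] - hand$t[i - 1] < 0.2) {
    i <- i - 1
  }
  t_onset <- hand$t[i]
  if (t_onset >= t_offset) {
    return(list(t_onset = NA_real_, t_offset = t_offset,
                offset_kind = offset_kind, flagged = TRUE))
  }
  list(t_onset = t_onset, t_offset = t_offset, offset_kind = offset_kind,
       flagged = FALSE)
}

#' Peak hand velocity toward the target
#'
#' Maximum of the +z (toward-wall) component of the central-difference
#' velocity of the smoothed controller position within the foreswing
#' window; floored at zero.
#'
#' @param hand smoothed motion tibble.
#' @param window a [detect_foreswing()] result.
#' @return m/s, or NA when the window holds fewer than 3 samples.
#' @export
peak_velocity <- function(hand, window) {
  if (isTRUE(window$flagged)) return(NA_real_)
  idx <- hand$t >= window$t_onset & hand$t <= window$t_offset
  if (sum(idx) < 3) return(NA_real_)
  vz <- central_diff(hand$cz[idx], hand$t[idx])
  max(max(vz), 0)
}

#' Transverse-plane range of motion
#'
#' For each sample, the angle in the horizontal plane between the headset's
#' facing direction and the head-to-hand displacement (both projected onto
#' the plane); ROM is the maximum over the foreswing window. Higher values
#' mean the hand rotated further around the body.
#'
#' @param head motion tibble with `hx`, `hz`, `hyaw` (headset).
#' @param hand motion tibble with `cx`, `cz` on the same clock (columns may
#'   live in the same tibble).
#' @param window a [detect_foreswing()] result.
#' @return degrees in `[0, 180]`, or NA when every sample is degenerate.
#' @export
range_of_motion <- function(head, hand, window) {
  if (isTRUE(window$flagged)) return(NA_real_)
  if (!identical(head$t, hand$t)) {
    hand <- tibble::tibble(t = head$t,
                           cx = approx(hand$t, hand$cx, head$t, rule = 2)$y,
                           cz = approx(hand$t, hand$cz, head$t, rule = 2)$y)
  }
  idx <- head$t >= window$t_onset & head$t <= window$t_offset
  if (!any(idx)) return(NA_real_)
  dx <- hand$cx[idx] - head$hx[idx]
  dz <- hand$cz[idx] - head$hz[idx]
  fx <- sin(deg2rad(head$hyaw[idx]))
  fz <- cos(deg2rad(head$hyaw[idx]))
  keep <- (dx^2 + dz^2) > 1e-12
  if (!any(keep)) return(NA_real_)
  dot <- (dx * fx + dz * fz)[keep]
  nrm <- sqrt(dx^2 + dz^2)[keep]
  ang <- rad2deg(acos(pmin(pmax(dot / nrm, -1), 1)))
  max(ang)
}

#' Interception rate over a set of trials
#'
#' @param intercepted logical vector (NA = flagged trial, ignored).
#' @return percentage of unflagged trials hit, or NA if all are flagged.
#' @export
interception_rate <- function(intercepted) {
  ok <- !is.na(intercepted)
  if (!any(ok)) return(NA_real_)
  100 * sum(intercepted[ok]) / sum(ok)
}

#' Run the kinematics pipeline on one trial
#'
#' Smooths the motion stream, detects contact and the foreswing window, and
#' extracts peak velocity and ROM.
#'
#' @param motion raw motion tibble (schema: t, hx, hy, hz, hyaw, hpitch,
#'   cx, cy, cz, cyaw, cpitch).
#' @param ball the trial's `"ball_trajectory"`.
#' @param cutoff smoothing cutoff in Hz (default 10).
#' @return one-row tibble: intercepted, t_contact, t_onset, t_offset,
#'   offset_kind, peak_velocity, rom, flagged.
#' @export
kinematics_trial <- function(motion, ball, cutoff = 10) {
  sm <- try(smooth_motion(motion, cutoff = cutoff), silent = TRUE)
  if (inherits(sm, "try-error")) {
    return(tibble::tibble(intercepted = NA, t_contact = NA_real_,
                          t_onset = NA_real_, t_offset = NA_real_,
                          offset_kind = NA_character_,
                          peak_velocity = NA_real_, rom = NA_real_,
                          flagged = TRUE))
  }
  ic <- detect_interception(sm, ball)
  fw <- detect_foreswing(sm, ball, ic$t_contact)
  tibble::tibble(
    intercepted = ic$intercepted, t_contact = ic$t_contact,
    t_onset = fw$t_onset, t_offset = fw$t_offset,
    offset_kind = fw$offset_kind,
    peak_velocity = peak_velocity(sm, fw),
    rom = range_of_motion(sm, sm, fw),
    flagged = fw$flagged
  )
}
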
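#' Gaze analysis pipeline
#'
#' Converts raw gaze direction samples into head-centred egocentric angles,
#' smooths them (three-frame median filter then a second-order Butterworth
#' low-pass at 15 Hz), detects fixations with a dispersion-threshold (I-DT)
#' algorithm (gaze steady within a 3 degree area for at least 100 ms),
#' applies the trial exclusion rules (tracking lost for more than 100 ms,
#' or more than 20% missing samples), and extracts the predictive
#' *bounce fixation*: the fixation occurring within 0.1 s of the ball
#' bounce or, failing that, immediately prior to it.
#'
#' @name gaze_pipeline
NULL

#' Convert gaze directions to head-centred egocentric angles
#'
#' Yaw is the signed horizontal angle of the gaze direction from the head's
#' facing axis (positive toward the dominant side), pitch the signed
#' vertical angle (positive up). Head orientation is interpolated onto the
#' gaze clock. Invalid samples keep their flag; their angles are computed
#' but should not be trusted.
#'
#' @param gaze tibble: t, gx, gy, gz (world-frame unit vectors), valid.
#' @param head motion tibble with `t`, `hyaw`, `hpitch`.
#' @return tibble: t, yaw, pitch, valid (degrees).
#' @export
to_egocentric <- function(gaze, head) {
  hyaw <- approx(head$t, head$hyaw, gaze$t, rule = 2)$y
  hpitch <- approx(head$t, head$hpitch, gaze$t, rule = 2)$y
  dirs <- cbind(gaze$gx, gaze$gy, gaze$gz)
  n <- nrow(dirs)
  yaw <- numeric(n); pitch <- numeric(n)
  # group samples by (rare) distinct head orientations for speed
  key <- paste(round(hyaw, 9), round(hpitch, 9))
  for (k in unique(key)) {
    idx <- which(key == k)
    ego <- world_to_ego(dirs[idx, , drop = FALSE], hyaw[idx[1]], hpitch[idx[1]])
    yaw[idx] <- ego$yaw
    pitch[idx] <- ego$pitch
  }
  tibble::tibble(t = gaze$t, yaw = wrap_deg(yaw), pitch = pitch,
                 valid = gaze$valid)
}

#' Smooth egocentric gaze angles
#'
#' Per channel: a three-frame median filter followed by a second-order
#' Butterworth low-pass at 15 Hz, applied forward and backward so the
#' result is zero-phase. Yaw is unwrapped before filtering to avoid the
#' +-180 degree seam. Invalid samples are excluded from the filter windows
#' by interpolating across them first; their validity flags are preserved.
#'
#' @param angles egocentric tibble (t, yaw, pitch, valid).
#' @param cutoff Hz (default 15).
#' @return tibble of the same shape with smoothed yaw/pitch.
#' @export
smooth_gaze <- function(angles, cutoff = 15) {
  dt <- diff(angles$t)
  if (any(abs(dt - dt[1]) > 1e-6)) stop("smooth_gaze requires uniform sampling")
  fs <- 1 / dt[1]
  if (nrow(angles) < 12) stop("stream too short for the filter warm-up")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  smooth1 <- function(y) {
    y[!angles$valid] <- NA
    y <- interp_na(y)
    y <- stats::runmed(y, 3, endrule = "keep")
    filtfilt_refl(bf, y)
  }
  yaw_u <- unwrap_deg(angles$yaw)
  out <- angles
  out$yaw <- wrap_deg(smooth1(yaw_u))
  out$pitch <- smooth1(angles$pitch)
  out
}

# Unwrap a degree sequence so consecutive differences stay within (-180, 180].
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  cumsum(c(x[1], d))
}

# Linear interpolation over NA values; endpoints extended.
interp_na <- function(y) {
  if (!anyNA(y)) return(y)
  ok <- which(!is.na(y))
  if (!length(ok)) stop("no valid samples to interpolate from")
  approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
}

# Dispersion of a window: maximum pairwise angular separation under the
# small-angle Euclidean metric on (yaw, pitch); or the Salvucci-style
# (max-min) yaw + (max-min) pitch sum.
gaze_dispersion <- function(yaw, pitch, metric = c("max_pairwise", "range_sum")) {
  metric <- match.arg(metric)
  if (metric == "range_sum") {
    return((max(yaw) - min(yaw)) + (max(pitch) - min(pitch)))
  }
  n <- length(yaw)
  if (n < 2) return(0)
  d2 <- outer(yaw, yaw, "-")^2 + outer(pitch, pitch, "-")^2
  sqrt(max(d2))
}

#' Detect fixations by spatial dispersion (I-DT)
#'
#' Sweeps a window forward while its dispersion stays within
#' `dispersion_max`; when the next sample would exceed it, the window is
#' emitted as a fixation if it lasts at least `min_duration`, otherwise the
#' start advances one sample. Emitted fixations are maximal, ordered and
#' non-overlapping. Invalid samples break windows. The default dispersion
#' metric is the maximum pairwise angular separation (small-angle Euclidean
#' on yaw/pitch); the classic range-sum variant is selectable.
#'
#' @param angles smoothed egocentric tibble.
#' @param dispersion_max degrees (default 3).
#' @param min_duration seconds (default 0.1).
#' @param metric dispersion metric, `"max_pairwise"` (default) or
#'   `"range_sum"`.
#' @return tibble: t_onset, t_offset, duration, centroid_yaw,
#'   centroid_pitch, n_samples.
#' @export
detect_fixations <- function(angles, dispersion_max = 3, min_duration = 0.1,
                             metric = "max_pairwise") {
  fix <- list()
  n <- nrow(angles)
  dt <- if (n > 1) angles$t[2] - angles$t[1] else 0
  runs <- rle(angles$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  yawv <- angles$yaw; pitchv <- angles$pitch
  for (r in which(runs$values)) {
    lo <- starts[r]; hi <- ends[r]
    i <- lo
    while (i <= hi) {
      j <- i
      # grow while dispersion stays within threshold (incremental update:
      # adding a point can only raise the max pairwise separation through
      # distances involving that point)
      if (metric == "max_pairwise") {
        dmax2 <- 0
        lim2 <- dispersion_max^2
        while (j < hi) {
          dy <- yawv[i:j] - yawv[j + 1]
          dp <- pitchv[i:j] - pitchv[j + 1]
          cand <- max(dmax2, max(dy * dy + dp * dp))
          if (cand > lim2) break
          dmax2 <- cand
          j <- j + 1
        }
      } else {
        ymin <- yawv[i]; ymax <- yawv[i]; pmin_ <- pitchv[i]; pmax_ <- pitchv[i]
        while (j < hi) {
          y2 <- yawv[j + 1]; p2 <- pitchv[j + 1]
          if ((max(ymax, y2) - min(ymin, y2)) +
              (max(pmax_, p2) - min(pmin_, p2)) > dispersion_max) break
          ymin <- min(ymin, y2); ymax <- max(ymax, y2)
          pmin_ <- min(pmin_, p2); pmax_ <- max(pmax_, p2)
          j <- j + 1
        }
      }
      dur <- (j - i + 1) * dt
      if (dur >= min_duration - 1e-9) {
        fix[[length(fix) + 1]] <- tibble::tibble(
          t_onset = angles$t[i], t_offset = angles$t[j], duration = dur,
          centroid_yaw = mean(angles$yaw[i:j]),
          centroid_pitch = mean(angles$pitch[i:j]),
          n_samples = j - i + 1L
        )
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (!length(fix)) {
    return(tibble::tibble(t_onset = numeric(), t_offset = numeric(),
                          duration = numeric(), centroid_yaw = numeric(),
                          centroid_pitch = numeric(), n_samples = integer()))
  }
  dplyr::bind_rows(fix)
}

#' Trial exclusion based on gaze signal quality
#'
#' A trial is excluded iff eye tracking was contiguously lost for more than
#' 100 ms or more than 20% of samples are missing (both strict
#' inequalities, so a gap of exactly 100 ms or exactly 20% missing is
#' retained).
#'
#' @param gaze raw gaze tibble with `t` and `valid`.
#' @param max_gap_s seconds (default 0.1).
#' @param max_missing_frac fraction (default 0.2).
#' @return list with `excluded` and `reason` (NA when retained).
#' @export
exclude_trial <- function(gaze, max_gap_s = 0.1, max_missing_frac = 0.2) {
  n <- nrow(gaze)
  dt <- if (n > 1) gaze$t[2] - gaze$t[1] else 0
  frac <- mean(!gaze$valid)
  r <- rle(gaze$valid)
  longest_gap <- if (any(!r$values)) max(r$lengths[!r$values]) * dt else 0
  if (longest_gap > max_gap_s + 1e-9) {
    list(excluded = TRUE, reason = sprintf("tracking lost %.0f ms", 1000 * longest_gap))
  } else if (frac > max_missing_frac + 1e-9) {
    list(excluded = TRUE, reason = sprintf("%.1f%% missing data", 100 * frac))
  } else {
    list(excluded = FALSE, reason = NA_character_)
  }
}

#' Select the predictive bounce fixation
#'
#' Picks the fixation whose interval intersects
#' `[t_bounce - window, t_bounce + window]`; among several, the one with
#' the latest onset (the most recent predictive commitment). If none
#' intersects, the fixation with the latest offset strictly before the
#' bounce is taken, provided it ends within `lookback` seconds of it.
#'
#' @param fixations tibble from [detect_fixations()], ordered by onset.
#' @param t_bounce bounce time, s.
#' @param window s (default 0.1).
#' @param lookback maximum gap for the "immediately prior" branch, s
#'   (default 0.5).
#' @return one-row tibble, or NULL when no qualifying fixation exists.
#' @export
bounce_fixation <- function(fixations, t_bounce, window = 0.1, lookback = 0.5) {
  if (!nrow(fixations)) return(NULL)
  lo <- t_bounce - window; hi <- t_bounce + window
  hitting <- fixations$t_onset <= hi & fixations$t_offset >= lo
  if (any(hitting)) {
    cand <- fixations[hitting, ]
    return(cand[which.max(cand$t_onset), ])
  }
  prior <- fixations$t_offset < t_bounce &
    fixations$t_offset >= t_bounce - lookback
  if (any(prior)) {
    cand <- fixations[prior, ]
    return(cand[which.max(cand$t_offset), ])
  }
  NULL
}

#' Run the gaze pipeline on one trial
#'
#' @param gaze raw gaze tibble.
#' @param head motion tibble (for head orientation).
#' @param t_bounce bounce time, s.
#' @param t_launch launch time used as the onset reference, s.
#' @param cutoff smoothing cutoff, Hz (default 15).
#' @param dispersion_max,min_duration I-DT thresholds (3 degrees, 0.1 s).
#' @param bounce_window bounce-fixation window, s (default 0.1).
#' @param max_gap_s,max_missing_frac exclusion limits (0.1 s, 0.2).
#' @return one-row tibble: excluded, reason, has_fixation, onset_rel_launch,
#'   duration, pitch, yaw.
#' @export
gaze_trial <- function(gaze, head, t_bounce, t_launch = 0, cutoff = 15,
                       dispersion_max = 3, min_duration = 0.1,
                       bounce_window = 0.1, max_gap_s = 0.1,
                       max_missing_frac = 0.2) {
  ex <- exclude_trial(gaze, max_gap_s, max_missing_frac)
  empty <- tibble::tibble(excluded = ex$excluded, reason = ex$reason,
                          has_fixation = FALSE, onset_rel_launch = NA_real_,
                          duration = NA_real_, pitch = NA_real_,
                          yaw = NA_real_)
  if (ex$excluded) return(empty)
  ego <- to_egocentric(gaze, head)
  sm <- smooth_gaze(ego, cutoff = cutoff)
  fx <- detect_fixations(sm, dispersion_max, min_duration)
  bf <- bounce_fixation(fx, t_bounce, window = bounce_window)
  if (is.null(bf)) return(empty)
  tibble::tibble(excluded = FALSE, reason = NA_character_, has_fixation = TRUE,
                 onset_rel_launch = bf$t_onset - t_launch,
                 duration = bf$duration, pitch = bf$centroid_pitch,
                 yaw = bf$centroid_yaw)
}

#' Aggregate bounce-fixation metrics per participant and condition
#'
#' Median onset time (relative to launch), mean duration, mean pitch and
#' the trial-to-trial standard deviation of pitch, over unexcluded trials
#' with a bounce fixation. Cells with fewer than `min_trials` contributing
#' trials are reported as missing.
#'
#' @param trials tibble of [gaze_trial()] rows.
#' @param min_trials minimum contributing trials per cell (default 2).
#' @return one-row tibble: n_trials, median_onset, mean_duration,
#'   mean_pitch, sd_pitch.
#' @export
aggregate_gaze <- function(trials, min_trials = 2) {
  ok <- trials[!trials$excluded & trials$has_fixation, ]
  if (nrow(ok) < min_trials) {
    return(tibble::tibble(n_trials = nrow(ok), median_onset = NA_real_,
                          mean_duration = NA_real_, mean_pitch = NA_real_,
                          sd_pitch = NA_real_))
  }
  tibble::tibble(
    n_trials = nrow(ok),
    median_onset = median(ok$onset_rel_launch),
    mean_duration = mean(ok$duration),
    mean_pitch = mean(ok$pitch),
    sd_pitch = sd(ok$pitch)
  )
}
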
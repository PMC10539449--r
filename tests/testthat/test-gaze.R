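make_head <- function(n, rate = 120, hyaw = 0, hpitch = 0) {
  tibble::tibble(t = (seq_len(n) - 1) / rate, hx = 0, hy = 1.7, hz = 0,
                 hyaw = rep_len(hyaw, n), hpitch = rep_len(hpitch, n))
}

test_that("egocentric conversion composes head and gaze frames correctly", {
  n <- 24
  head <- make_head(n)
  # gaze along the head's facing axis: (0, 0)
  g <- tibble::tibble(t = head$t, gx = 0, gy = 0, gz = 1, valid = TRUE)
  ego <- to_egocentric(g, head)
  expect_equal(ego$yaw, rep(0, n), tolerance = 1e-12)
  expect_equal(ego$pitch, rep(0, n), tolerance = 1e-12)
  # head pitched up 10 degrees, gaze world-horizontal: pitch -10
  ego2 <- to_egocentric(g, make_head(n, hpitch = 10))
  expect_equal(ego2$pitch, rep(-10, n), tolerance = 1e-9)
  # random orientations against a rotation-matrix oracle
  withr::with_seed(5, {
    for (rep in 1:25) {
      hy <- runif(1, -170, 170); hp <- runif(1, -80, 80)
      yaw <- runif(1, -60, 60); pitch <- runif(1, -60, 60)
      dir <- vrracquet:::ego_to_world(yaw, pitch, hy, hp)
      g1 <- tibble::tibble(t = head$t[1:12], gx = dir[1], gy = dir[2],
                           gz = dir[3], valid = TRUE)
      ego3 <- to_egocentric(g1, make_head(12, hyaw = hy, hpitch = hp))
      expect_equal(ego3$yaw[1], yaw, tolerance = 1e-9)
      expect_equal(ego3$pitch[1], pitch, tolerance = 1e-9)
    }
  })
})

test_that("gaze smoothing kills single-sample spikes and preserves slow signal", {
  n <- 240
  yaw <- rep(5, n); yaw[120] <- 35 # width-1 outlier
  ang <- make_angles(yaw, rep(-20, n))
  sm <- smooth_gaze(ang)
  expect_lt(max(abs(sm$yaw - 5)), 0.5)
  expect_equal(sm$pitch, rep(-20, n), tolerance = 1e-9) # constant unchanged
  # 2 Hz sinusoid: attenuation matches the dual-pass closed-form gain to 1%
  t <- (0:719) / 120
  pitch <- 3 * sin(2 * pi * 2 * t)
  sm2 <- smooth_gaze(make_angles(rep(0, 720), pitch))
  mid <- 150:570
  gain <- max(abs(sm2$pitch[mid])) / 3
  expect_equal(gain, 1 / (1 + (2 / 15)^4), tolerance = 0.01)
  expect_error(smooth_gaze(make_angles(1:5, 1:5)), "short")
})

test_that("smoothing respects the yaw seam and invalid samples", {
  n <- 240
  yaw <- rep(c(179.5, -179.5), n / 2) # oscillating across the seam
  sm <- smooth_gaze(make_angles(yaw, rep(0, n)))
  expect_true(all(abs(abs(sm$yaw) - 180) < 1)) # no excursion through 0
  # invalid samples are bridged, not zero-filled
  pitch <- rep(-20, n)
  valid <- rep(TRUE, n); valid[100:104] <- FALSE
  ang <- make_angles(rep(0, n), pitch, valid = valid)
  ang$pitch[100:104] <- 999 # garbage behind the invalid flag
  sm2 <- smooth_gaze(ang)
  expect_lt(max(abs(sm2$pitch - (-20))), 1e-6)
  expect_identical(sm2$valid, valid)
})

test_that("I-DT detection matches definitions on canonical cases", {
  # 150 ms of steady gaze: one fixation of duration 0.15
  n <- 18
  fx <- detect_fixations(make_angles(rep(1, n), rep(2, n)))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, 0.15)
  expect_equal(fx$centroid_yaw, 1)
  expect_equal(fx$centroid_pitch, 2)
  # alternating +-5 degrees: no fixation
  fx2 <- detect_fixations(make_angles(rep(c(-5, 5), 60), rep(0, 120)))
  expect_equal(nrow(fx2), 0)
  # translation invariance of dispersion
  withr::with_seed(6, {
    yaw <- cumsum(rnorm(300, 0, 0.8)); pitch <- cumsum(rnorm(300, 0, 0.8))
    a <- detect_fixations(make_angles(yaw, pitch))
    b <- detect_fixations(make_angles(yaw + 40, pitch - 25))
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$t_onset, b$t_onset)
    expect_equal(a$centroid_yaw + 40, b$centroid_yaw)
  })
})

test_that("detected fixations meet both thresholds and are maximal", {
  withr::with_seed(7, {
    yaw <- cumsum(rnorm(500, 0, 0.6)); pitch <- cumsum(rnorm(500, 0, 0.6))
    ang <- make_angles(yaw, pitch)
    fx <- detect_fixations(ang)
    expect_gt(nrow(fx), 0)
    for (i in seq_len(nrow(fx))) {
      idx <- which(ang$t >= fx$t_onset[i] & ang$t <= fx$t_offset[i])
      expect_gte(fx$duration[i], 0.1)
      expect_lte(vrracquet:::gaze_dispersion(yaw[idx], pitch[idx]), 3)
    }
    # non-overlapping and ordered
    if (nrow(fx) > 1) {
      expect_true(all(diff(fx$t_onset) > 0))
      expect_true(all(fx$t_onset[-1] > fx$t_offset[-nrow(fx)]))
    }
  })
})

test_that("exclusion rules use strict inequalities at the stated limits", {
  n <- 120 # one second at 120 Hz
  mk <- function(invalid_idx) {
    v <- rep(TRUE, n); v[invalid_idx] <- FALSE
    tibble::tibble(t = (0:(n - 1)) / 120, gx = 0, gy = 0, gz = 1, valid = v)
  }
  # 0.15 s contiguous gap (18 samples): excluded by the gap rule
  ex <- exclude_trial(mk(1:18))
  expect_true(ex$excluded)
  expect_match(ex$reason, "lost")
  # 25% scattered: excluded by the fraction rule
  ex2 <- exclude_trial(mk(seq(1, 120, by = 4)))
  expect_true(ex2$excluded)
  expect_match(ex2$reason, "missing")
  # exactly 0.100 s gap (12 samples) and exactly 20% missing: retained
  idx <- c(1:12, seq(20, 115, length.out = 12))
  stopifnot(length(unique(round(idx))) == 24) # 24/120 = 20%
  ex3 <- exclude_trial(mk(unique(round(idx))))
  expect_false(ex3$excluded)
  # monotone: adding invalid samples never un-excludes
  base_idx <- 1:18
  ex4 <- exclude_trial(mk(c(base_idx, 50:60)))
  expect_true(ex4$excluded)
})

test_that("bounce fixation selection follows the window-then-prior rule", {
  fx <- tibble::tibble(t_onset = c(0.2, 1.0, 1.45), t_offset = c(0.4, 1.2, 1.7),
                       duration = c(0.2, 0.2, 0.25),
                       centroid_yaw = 1:3, centroid_pitch = 4:6,
                       n_samples = c(24L, 24L, 30L))
  # fixation spanning the bounce wins
  sel <- bounce_fixation(fx, t_bounce = 1.58)
  expect_equal(sel$centroid_pitch, 6)
  # several intersecting: latest onset
  fx2 <- fx; fx2$t_offset[2] <- 1.5
  sel2 <- bounce_fixation(fx2, t_bounce = 1.55)
  expect_equal(sel2$centroid_pitch, 6)
  # only a fixation ending 0.3 s before the bounce: the "immediately prior" branch
  sel3 <- bounce_fixation(fx[1:2, ], t_bounce = 1.5)
  expect_equal(sel3$centroid_pitch, 5)
  # nothing within the lookback: absent
  expect_null(bounce_fixation(fx[1, ], t_bounce = 1.5))
  expect_null(bounce_fixation(fx[0, ], t_bounce = 1.5))
})

test_that("gaze aggregation yields the stated cell statistics", {
  tr <- tibble::tibble(excluded = FALSE, has_fixation = TRUE,
                       onset_rel_launch = c(1, 2, 10),
                       duration = c(0.2, 0.3, 0.4),
                       pitch = c(-15, -15, -15))
  agg <- aggregate_gaze(tr)
  expect_equal(agg$median_onset, 2)
  expect_equal(agg$mean_duration, 0.3)
  expect_equal(agg$sd_pitch, 0)
  expect_true(is.na(aggregate_gaze(tr[1, ])$mean_pitch)) # < 2 trials
  # Monte-Carlo consistency: recovered pitch SD approaches the noise sigma
  withr::with_seed(11, {
    n <- 4000
    trmc <- tibble::tibble(excluded = FALSE, has_fixation = TRUE,
                           onset_rel_launch = 1.3, duration = 0.4,
                           pitch = rnorm(n, -16, 2.5))
    expect_equal(aggregate_gaze(trmc)$sd_pitch, 2.5, tolerance = 0.05)
  })
})

test_that("noiseless agent pitch survives the full gaze pipeline to 0.1 degree", {
  p <- noiseless_params()
  for (belief in c(0, 0.5)) {
    tr <- make_clean_trial(params = p, belief = belief, seed = 21)
    g <- gaze_trial(tr$raw$gaze, tr$raw$motion, tr$traj$t_bounce)
    expect_false(g$excluded)
    expect_true(g$has_fixation)
    expect_lt(abs(g$pitch - tr$raw$truth$pitch_fix), 0.1)
  }
})
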
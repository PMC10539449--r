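make_stream <- function(cz, rate = 90, cx = 0, cy = 1) {
  n <- length(cz)
  tibble::tibble(t = (seq_len(n) - 1) / rate, hx = 0, hy = 1.7, hz = 0,
                 hyaw = 0, hpitch = 0, cx = rep_len(cx, n),
                 cy = rep_len(cy, n), cz = cz, cyaw = 0, cpitch = 0)
}

test_that("motion smoothing is zero-phase, DC-preserving, and passband-flat", {
  s <- make_stream(rep(0.4, 200))
  out <- smooth_motion(s)
  expect_equal(out$cz, s$cz, tolerance = 1e-9)
  # symmetric bump: peak sample unmoved
  z <- exp(-((1:200) - 100)^2 / 50)
  out <- smooth_motion(make_stream(z))
  expect_equal(which.max(out$cz), 100)
  # 1 Hz sinusoid at 90 Hz sampling, 10 Hz cutoff: < 1% attenuation, and the
  # measured gain matches the dual-pass analog magnitude response
  t <- (0:899) / 90
  z <- sin(2 * pi * 1 * t)
  out <- smooth_motion(make_stream(z))
  mid <- 200:700 # avoid filter edges
  gain <- max(abs(out$cz[mid])) / max(abs(z[mid]))
  expect_gt(gain, 0.99)
  analog_gain <- 1 / (1 + (1 / 10)^4) # |H|^2 of a 2nd-order butterworth, dual pass
  expect_equal(gain, analog_gain, tolerance = 0.01)
  expect_error(smooth_motion(make_stream(rep(0, 5))), "short")
})

test_that("filtering commutes with differentiation within tolerance", {
  withr::with_seed(4, {
    t <- (0:599) / 90
    z <- cumsum(rnorm(600, sd = 0.01))
    s <- make_stream(z)
    v_then_f <- smooth_motion(make_stream(vrracquet:::central_diff(z, t)))$cz
    f_then_v <- vrracquet:::central_diff(smooth_motion(s)$cz, t)
    mid <- 50:550
    expect_equal(v_then_f[mid], f_then_v[mid], tolerance = 1e-6)
  })
})

test_that("interception detection follows the inflated-box contact rule", {
  ball <- simulate_trajectory(launch_spec(elasticity = 0.65))
  t_cross <- ball_crossing_time(ball, 1.0)
  y_cross <- ball_state_at(ball, t_cross)$position[2]
  n <- ceiling(ball$t_end * 90)
  # racquet parked at the crossing point: contact at the crossing
  hit <- make_stream(rep(1.0, n), cx = 0.75, cy = y_cross)
  res <- detect_interception(hit, ball)
  expect_true(res$intercepted)
  expect_lt(abs(res$t_contact - t_cross), 0.02)
  # racquet 1 m to the side: no contact
  res2 <- detect_interception(make_stream(rep(1.0, n), cx = 0.75 - 1,
                                          cy = y_cross), ball)
  expect_false(res2$intercepted)
  # grazing pass at exactly halfext + radius (closed boundary) still hits
  graze <- make_stream(rep(1.0, n), cx = 0.75 - (0.30 + 0.0335),
                       cy = y_cross)
  expect_true(detect_interception(graze, ball)$intercepted)
  beyond <- make_stream(rep(1.0, n), cx = 0.75 - (0.30 + 0.0335 + 0.01),
                        cy = y_cross)
  expect_false(detect_interception(beyond, ball)$intercepted)
})

test_that("foreswing detection finds the last sustained forward motion", {
  ball <- simulate_trajectory(launch_spec(elasticity = 0.65))
  # synthetic minimum-jerk swing with known onset
  t <- seq(0, ball$t_end, by = 1 / 90)
  t_on <- 1.6; T_sw <- 0.5
  x <- pmin(pmax((t - t_on) / T_sw, 0), 1)
  cz <- 0.2 + 0.8 * (10 * x^3 - 15 * x^4 + 6 * x^5)
  s <- smooth_motion(make_stream(cz))
  fw <- detect_foreswing(s, ball, t_contact = 2.2)
  expect_false(fw$flagged)
  expect_equal(fw$t_offset, 2.2)          # contact time taken exactly
  expect_equal(fw$offset_kind, "contact")
  expect_lt(abs(fw$t_onset - t_on), 2.5 / 90) # within ~2 samples of truth
  # stationary hand on a miss: flagged, offset = ball passing the racquet
  still <- smooth_motion(make_stream(rep(0.5, length(t))))
  fw2 <- detect_foreswing(still, ball, t_contact = NA)
  expect_true(fw2$flagged)
  expect_equal(fw2$offset_kind, "ball_passed")
})

test_that("peak velocity projects onto the target direction", {
  t <- (0:299) / 90
  s <- make_stream(2 * t) # constant 2 m/s toward the wall
  w <- list(t_onset = 0.5, t_offset = 2.5, flagged = FALSE)
  expect_equal(peak_velocity(s, w), 2, tolerance = 1e-6)
  # pure lateral motion: projection is zero (negative maxima floor at 0)
  s2 <- make_stream(rep(0.5, 300), cx = 2 * t)
  expect_equal(peak_velocity(s2, w), 0)
  # minimum-jerk swing: peak = 1.875 A / T within 1% after smoothing
  t <- seq(0, 3, by = 1 / 90)
  A <- 0.8; T_sw <- 0.5; t_on <- 1.2
  x <- pmin(pmax((t - t_on) / T_sw, 0), 1)
  s3 <- smooth_motion(make_stream(0.1 + A * (10 * x^3 - 15 * x^4 + 6 * x^5)))
  w3 <- list(t_onset = t_on, t_offset = t_on + T_sw, flagged = FALSE)
  expect_equal(peak_velocity(s3, w3), 1.875 * A / T_sw, tolerance = 0.01)
})

test_that("range of motion equals the brute-force per-sample angle maximum", {
  # hand straight ahead: zero; hand at 90 degrees: ninety
  s0 <- make_stream(rep(1, 90), cx = 0)
  w <- list(t_onset = 0, t_offset = 1, flagged = FALSE)
  expect_equal(range_of_motion(s0, s0, w), 0, tolerance = 1e-9)
  s90 <- make_stream(rep(0, 90), cx = 1)
  expect_equal(range_of_motion(s90, s90, w), 90, tolerance = 1e-9)
  # randomized poses against the oracle
  withr::with_seed(8, {
    for (rep in 1:20) {
      n <- 60
      s <- tibble::tibble(t = (0:(n - 1)) / 90,
                          hx = rnorm(n, 0, 0.1), hy = 1.7,
                          hz = rnorm(n, 0, 0.1),
                          hyaw = runif(n, -180, 180), hpitch = 0,
                          cx = rnorm(n, 0, 0.8), cy = 1,
                          cz = rnorm(n, 0.3, 0.8), cyaw = 0, cpitch = 0)
      got <- range_of_motion(s, s, list(t_onset = 0, t_offset = 1,
                                        flagged = FALSE))
      want <- oracle_rom(s$hx, s$hz, s$hyaw, s$cx, s$cz)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("ROM is invariant to a global rotation of the world frame", {
  withr::with_seed(9, {
    n <- 80
    s <- make_stream(runif(n, 0.2, 1), cx = runif(n, -0.5, 0.9))
    s$hyaw <- runif(n, -30, 30)
    w <- list(t_onset = 0, t_offset = 1, flagged = FALSE)
    base <- range_of_motion(s, s, w)
    th <- deg <- 37
    R <- matrix(c(cos(th * pi / 180), -sin(th * pi / 180),
                  sin(th * pi / 180), cos(th * pi / 180)), 2, 2)
    rot <- s
    hxz <- cbind(s$hx, s$hz) %*% t(R)
    cxz <- cbind(s$cx, s$cz) %*% t(R)
    rot$hx <- hxz[, 1]; rot$hz <- hxz[, 2]
    rot$cx <- cxz[, 1]; rot$cz <- cxz[, 2]
    rot$hyaw <- s$hyaw + deg
    expect_equal(range_of_motion(rot, rot, w), base, tolerance = 1e-9)
  })
})

test_that("interception rate handles hits, misses and flagged trials", {
  expect_equal(interception_rate(rep(TRUE, 45)), 100)
  expect_equal(interception_rate(rep(FALSE, 10)), 0)
  expect_equal(interception_rate(c(rep(TRUE, 30), rep(FALSE, 15))), 66.67,
               tolerance = 1e-4)
  expect_equal(interception_rate(c(TRUE, NA, FALSE, NA)), 50)
  expect_true(is.na(interception_rate(c(NA, NA))))
})

test_that("the pipeline recovers noiseless ground truth within stated tolerances", {
  p <- noiseless_params(rom_base = 72, swing_peak_velocity_mean = 2.2)
  for (e in c(0.65, 0.85)) {
    tr <- make_clean_trial(params = p, elasticity = e, belief = 0.4, seed = 3)
    m <- kinematics_trial(tr$raw$motion, tr$raw$ball)
    expect_false(m$flagged)
    expect_identical(m$intercepted, tr$raw$events$intercepted)
    expect_lt(abs(m$rom - tr$raw$truth$rom), 1)
    expect_lt(abs(m$peak_velocity - tr$raw$truth$v_peak) / tr$raw$truth$v_peak,
              0.02)
  }
})

test_that("rotation angle yaw checks out for world-rotation fixture", {
  # direction convention sanity: yaw 90 points along +x
  ax <- vrracquet:::head_axes(90, 0)
  expect_equal(ax$forward, c(1, 0, 0), tolerance = 1e-12)
})
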
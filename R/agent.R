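#' Synthetic participants for the racquetball task
#'
#' Agents hold a scalar belief `b = P(bouncy)` updated trial-by-trial with a
#' delta rule, blend it linearly with the explicit probabilistic cue when one
#' is shown, and translate the resulting *effective belief* into behaviour:
#'
#' * the predictive bounce fixation is placed at a pitch of
#'   `pitch_bias + pitch_gain * E[post-bounce apex | effective belief]`,
#'   where the expected apex is the belief-weighted mixture of the two ball
#'   types' apex heights;
#' * transverse range of motion (ROM) shrinks with the binary entropy of the
#'   effective belief (`rom_base - rom_uncertainty_slope * H(b_eff)`),
#'   mimicking the freezing of movement degrees of freedom under
#'   uncertainty;
#' * the foreswing is a minimum-jerk reach timed to meet the ball at a
#'   fixed interception plane, with a Gaussian arrival-time error whose
#'   standard deviation (`timing_noise_sd`) governs interception success.
#'
#' The generator emits raw 90 Hz headset/controller streams and 120 Hz gaze
#' streams so every downstream pipeline stage can be exercised without real
#' recordings.
#'
#' @name synthetic_agent
NULL

RACQUET_HALFEXT <- c(0.30, 0.15, 0.005) # half-extents of the 0.6 x 0.3 x 0.01 m racquet
BALL_RADIUS <- 0.0335                    # standard tennis ball, contact detection only
MOTION_RATE <- 90
GAZE_RATE <- 120
EYE_HEIGHT <- 1.7
HAND_REACH <- 1.0       # head-to-racquet-centre radius during the swing, m
INTERCEPT_PLANE_Z <- 1.0 # depth at which agents aim to meet the ball, m
REST_POS <- c(0.35, 1.00, 0.55)
BACKSWING_HEIGHT <- 1.05
BACKSWING_DUR <- 0.35
BACKSWING_GAP <- 0.08    # hold between backswing end and foreswing onset, s
FIX_LEAD <- 0.25         # fixation onset before the bounce, s
SACCADE_DUR <- 0.025 # ~10 deg saccades complete in a few samples at 120 Hz

#' Agent parameters
#'
#' @param learning_rate delta-rule learning rate, in `[0, 1]`.
#' @param cue_weight reliance on the explicit cue, in `[0, 1]`.
#' @param gaze_noise_sd degrees; pursuit sample noise and trial-to-trial
#'   fixation placement noise.
#' @param pitch_gain degrees of fixation elevation per metre of expected
#'   post-bounce apex.
#' @param pitch_bias degrees; fixation pitch when the expected apex is zero.
#' @param rom_base degrees; ROM at zero belief entropy.
#' @param rom_uncertainty_slope degrees of ROM lost per bit of belief entropy.
#' @param rom_noise_sd degrees; trial-level ROM noise.
#' @param swing_peak_velocity_mean,swing_peak_velocity_sd m/s; per-trial peak
#'   foreswing velocity toward the wall.
#' @param timing_noise_sd s; standard deviation of the racquet arrival-time
#'   error (positive errors mean arriving late).
#' @param fixation_hold_s s; fixation duration, at least 0.1 so a detectable
#'   bounce fixation exists on every clean trial.
#' @param dropout_rate per-sample probability that a gaze sample is invalid.
#' @param gap_rate expected number of contiguous tracking-loss gaps per trial.
#' @param gap_dur_range s; min/max duration of a contiguous gap.
#' @return list of class `"agent_params"`.
#' @export
agent_params <- function(learning_rate = 0.3, cue_weight = 0.5,
                         gaze_noise_sd = 0.3, pitch_gain = 9, pitch_bias = -32,
                         rom_base = 85, rom_uncertainty_slope = 20,
                         rom_noise_sd = 2,
                         swing_peak_velocity_mean = 2.0,
                         swing_peak_velocity_sd = 0.15,
                         timing_noise_sd = 0.05,
                         fixation_hold_s = 0.4,
                         dropout_rate = 0.01, gap_rate = 0.03,
                         gap_dur_range = c(0.05, 0.15)) {
  p <- as.list(environment())
  stopifnot(learning_rate >= 0, learning_rate <= 1,
            cue_weight >= 0, cue_weight <= 1,
            gaze_noise_sd >= 0, rom_noise_sd >= 0,
            swing_peak_velocity_sd >= 0, timing_noise_sd >= 0)
  if (fixation_hold_s < 0.1) stop("fixation_hold_s must be >= 0.1 s")
  structure(p, class = "agent_params")
}

#' Delta-rule belief update
#'
#' `b' = b + alpha * (outcome - b)`, clamped to `[0, 1]`.
#'
#' @param b current belief P(bouncy).
#' @param outcome observed ball type, 1 = bouncy, 0 = normal.
#' @param alpha learning rate in `[0, 1]`.
#' @return updated belief.
#' @export
update_belief <- function(b, outcome, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot(all(b >= 0 & b <= 1), all(outcome %in% c(0, 1)))
  pmin(pmax(b + alpha * (outcome - b), 0), 1)
}

#' Blend the learned belief with an explicit cue
#'
#' With a cue present the effective belief is
#' `w * cue_p_bouncy + (1 - w) * b`; without one it is `b` unchanged.
#'
#' @param b learned belief P(bouncy).
#' @param cue_p_bouncy cued bouncy probability, or `NA`/`NULL` when no cue is
#'   shown.
#' @param w cue weight in `[0, 1]`.
#' @return effective belief.
#' @export
effective_belief <- function(b, cue_p_bouncy, w) {
  stopifnot(all(b >= 0 & b <= 1), w >= 0, w <= 1)
  if (is.null(cue_p_bouncy) || length(cue_p_bouncy) == 0 || is.na(cue_p_bouncy)) {
    return(b)
  }
  w * cue_p_bouncy + (1 - w) * b
}

# Expected post-bounce apex (m) under belief b: linear mixture of the two
# ball types' apex heights.
expected_apex <- function(b, vz_at_bounce = 9, gravity = 9.8) {
  apex_n <- (0.65 * vz_at_bounce)^2 / (2 * gravity)
  apex_b <- (0.85 * vz_at_bounce)^2 / (2 * gravity)
  (1 - b) * apex_n + b * apex_b
}

# Head frame axes from yaw/pitch in degrees. Yaw about +y (positive toward
# +x), pitch positive up. Returns list(forward, right, up).
head_axes <- function(yaw, pitch) {
  psi <- deg2rad(yaw); th <- deg2rad(pitch)
  f <- c(sin(psi) * cos(th), sin(th), cos(psi) * cos(th))
  r <- c(cos(psi), 0, -sin(psi))
  u <- c(f[2] * r[3] - f[3] * r[2],
         f[3] * r[1] - f[1] * r[3],
         f[1] * r[2] - f[2] * r[1])
  list(forward = f, right = r, up = u)
}

# Egocentric (yaw, pitch) degrees -> world unit vectors, given head yaw/pitch.
ego_to_world <- function(yaw, pitch, head_yaw = 0, head_pitch = 0) {
  ax <- head_axes(head_yaw, head_pitch)
  cy <- cos(deg2rad(yaw)); sy <- sin(deg2rad(yaw))
  cp <- cos(deg2rad(pitch)); sp <- sin(deg2rad(pitch))
  gx_h <- sy * cp; gy_h <- sp; gz_h <- cy * cp
  cbind(gx_h) %*% rbind(ax$right) + cbind(gy_h) %*% rbind(ax$up) +
    cbind(gz_h) %*% rbind(ax$forward)
}

# World direction (rows) -> egocentric yaw/pitch degrees for a static head.
world_to_ego <- function(dirs, head_yaw = 0, head_pitch = 0) {
  ax <- head_axes(head_yaw, head_pitch)
  gr <- dirs %*% ax$right
  gu <- dirs %*% ax$up
  gf <- dirs %*% ax$forward
  list(yaw = rad2deg(atan2(gr, gf))[, 1],
       pitch = rad2deg(asin(pmin(pmax(gu, -1), 1)))[, 1])
}

# Ball-centre inside the racquet's oriented box inflated by the ball radius?
# `rel` are ball positions relative to the racquet centre (rows), already in
# the racquet frame.
in_racquet_box <- function(rel, halfext = RACQUET_HALFEXT, radius = BALL_RADIUS) {
  lim <- halfext + radius
  abs(rel[, 1]) <= lim[1] & abs(rel[, 2]) <= lim[2] & abs(rel[, 3]) <= lim[3]
}

# Analytic swing plan for one trial. Returns control-point geometry and key
# times; positions are evaluated lazily by swing_position().
plan_swing <- function(rom_deg, v_peak, traj, tau) {
  t_cross <- ball_crossing_time(traj, INTERCEPT_PLANE_Z)
  y_cross <- ball_state_at(traj, t_cross)$position[2]
  th <- deg2rad(rom_deg)
  p0 <- c(HAND_REACH * sin(th), BACKSWING_HEIGHT, HAND_REACH * cos(th))
  p1 <- c(traj$bounce_point[1], y_cross, INTERCEPT_PLANE_Z)
  A_z <- p1[3] - p0[3]
  if (A_z <= 0.05) stop("infeasible swing: backswing already at the interception plane")
  T_sw <- 1.875 * A_z / v_peak
  t_arrive <- t_cross + tau
  # a swing cannot start before the trial does: cap its duration (raising the
  # effective peak velocity) and compress the backswing when time is short
  T_max <- t_arrive - 0.20
  if (T_max <= 0.05) stop("infeasible hold durations: arrival too early for any swing")
  if (T_sw > T_max) T_sw <- T_max
  t_on <- t_arrive - T_sw
  bs_dur <- min(BACKSWING_DUR, max(t_on - BACKSWING_GAP - 0.05, 0.08))
  t_bs <- t_on - BACKSWING_GAP - bs_dur
  if (t_bs < 0.02) stop("infeasible hold durations: backswing would start before launch")
  list(p_rest = REST_POS, p0 = p0, p1 = p1, T_sw = T_sw,
       v_peak_eff = 1.875 * A_z / T_sw, bs_dur = bs_dur,
       t_bs = t_bs, t_on = t_on, t_arrive = t_arrive, t_cross = t_cross,
       y_cross = y_cross)
}

# Controller position at arbitrary times under a swing plan.
swing_position <- function(t, plan) {
  pos <- matrix(plan$p_rest, nrow = length(t), ncol = 3, byrow = TRUE)
  bs_end <- plan$t_bs + plan$bs_dur
  in_bs <- t >= plan$t_bs & t < bs_end
  pos[in_bs, ] <- minjerk_path(t[in_bs], plan$t_bs, plan$bs_dur, plan$p_rest, plan$p0)
  in_hold <- t >= bs_end & t < plan$t_on
  if (any(in_hold)) {
    pos[in_hold, ] <- matrix(plan$p0, nrow = sum(in_hold), ncol = 3, byrow = TRUE)
  }
  in_fs <- t >= plan$t_on
  pos[in_fs, ] <- minjerk_path(t[in_fs], plan$t_on, plan$T_sw, plan$p0, plan$p1)
  pos
}

# Ground-truth contact from the analytic swing and ball paths, evaluated on a
# 1 kHz grid (independent of the 90 Hz stream the pipelines see).
analytic_contact <- function(plan, traj, t_end) {
  t0 <- max(0, plan$t_on - 0.05)
  if (t0 >= t_end) return(NA_real_) # swing starts after the ball is gone
  t <- seq(t0, t_end, by = 0.001)
  ball <- ball_state_at(traj, t)$position
  racq <- swing_position(t, plan)
  hit <- in_racquet_box(ball - racq)
  if (any(hit)) t[which(hit)[1]] else NA_real_
}

# Trial-level behavioural draws shared by the stream generator and the fast
# metrics-only cohort mode. Same seed -> same behaviour in both modes.
draw_trial_behavior <- function(trial, belief, params, seed) {
  trial <- as.list(trial)
  cue_p <- if (isTRUE(trial$cued)) trial$bouncy_pct / 100 else NA_real_
  b_eff <- effective_belief(belief, cue_p, params$cue_weight)
  with_seed(derive_seed(seed, "beh"), {
    # arrival-time error; clamped to a plausible range (a swing a second out
    # is already a certain miss, and the trial must still contain it)
    tau <- min(max(rnorm(1, 0, params$timing_noise_sd), -0.8), 1.2)
    v_peak <- max(0.8, rnorm(1, params$swing_peak_velocity_mean,
                             params$swing_peak_velocity_sd))
    rom <- params$rom_base -
      params$rom_uncertainty_slope * binary_entropy(b_eff) +
      rnorm(1, 0, params$rom_noise_sd)
    rom <- min(max(rom, 45), 110)
    pitch_fix <- params$pitch_bias + params$pitch_gain * expected_apex(b_eff) +
      rnorm(1, 0, params$gaze_noise_sd)
    list(tau = tau, v_peak = v_peak, rom = rom, pitch_fix = pitch_fix,
         belief = belief, effective_belief = b_eff)
  })
}

#' Generate raw streams for a single trial
#'
#' Synthesises the 90 Hz motion stream (static headset plus the planned
#' swing) and the 120 Hz gaze stream (smooth pursuit of the ball, a saccade
#' to the predictive bounce fixation held for `fixation_hold_s`, then
#' pursuit again), together with ground-truth event times and the intended
#' metric values used by the recovery tests.
#'
#' @param trial one row of a block plan's `trials` tibble (list or
#'   single-row data frame).
#' @param traj the trial's [simulate_trajectory()] output.
#' @param belief current belief P(bouncy) entering the trial.
#' @param params an [agent_params()].
#' @param seed integer seed for this trial's noise draws.
#' @return list with `motion`, `gaze` (tibbles in the documented stream
#'   schemas), `events` (t_launch, t_bounce, t_contact, t_pass, intercepted)
#'   and `truth` (intended ROM, fixation pitch/yaw, peak velocity, timing
#'   error, effective belief).
#' @export
generate_trial <- function(trial, traj, belief, params, seed) {
  beh <- draw_trial_behavior(trial, belief, params, seed)
  tau <- beh$tau; v_peak <- beh$v_peak; rom <- beh$rom
  pitch_fix <- beh$pitch_fix; b_eff <- beh$effective_belief
  plan <- plan_swing(rom, v_peak, traj, tau)
  t_end <- max(traj$t_end, plan$t_arrive + 0.15)
  t_contact <- analytic_contact(plan, traj, min(t_end, traj$t_end))
  with_seed(derive_seed(seed, "stream"), {
    # --- motion stream (90 Hz) ---
    tm <- seq(0, t_end, by = 1 / MOTION_RATE)
    hand <- swing_position(tm, plan)
    motion <- tibble::tibble(
      t = tm,
      hx = 0, hy = EYE_HEIGHT, hz = 0, hyaw = 0, hpitch = 0,
      cx = hand[, 1], cy = hand[, 2], cz = hand[, 3],
      cyaw = 0, cpitch = 0
    )

    # --- gaze stream (120 Hz) ---
    tg <- seq(0, t_end, by = 1 / GAZE_RATE)
    n <- length(tg)
    # saccade-landing jitter; absent in fully noiseless agents
    jit <- if (params$gaze_noise_sd > 0) {
      min(max(rnorm(1, 0, 0.04), -0.1), 0.1)
    } else 0
    fix_on <- traj$t_bounce - FIX_LEAD + jit
    fix_off <- fix_on + params$fixation_hold_s
    ball_pos <- ball_state_at(traj, pmin(tg, traj$t_end))$position
    dirs <- ball_pos - matrix(c(0, EYE_HEIGHT, 0), n, 3, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ego <- world_to_ego(dirs)
    yaw <- ego$yaw + rnorm(n, 0, params$gaze_noise_sd)
    pitch <- ego$pitch + rnorm(n, 0, params$gaze_noise_sd)
    bp_dir <- traj$bounce_point - c(0, EYE_HEIGHT, 0)
    yaw_fix <- rad2deg(atan2(bp_dir[1], bp_dir[3]))
    in_fix <- tg >= fix_on & tg <= fix_off
    yaw[in_fix] <- yaw_fix
    pitch[in_fix] <- pitch_fix
    in_sac <- tg >= fix_on - SACCADE_DUR & tg < fix_on
    if (any(in_sac)) {
      w <- (tg[in_sac] - (fix_on - SACCADE_DUR)) / SACCADE_DUR
      i0 <- max(which(in_sac)[1] - 1, 1)
      yaw[in_sac] <- (1 - w) * yaw[i0] + w * yaw_fix
      pitch[in_sac] <- (1 - w) * pitch[i0] + w * pitch_fix
    }
    gdir <- ego_to_world(yaw, pitch)
    valid <- runif(n) >= params$dropout_rate
    n_gaps <- stats::rpois(1, params$gap_rate)
    if (n_gaps > 0) {
      for (k in seq_len(n_gaps)) {
        dur <- runif(1, params$gap_dur_range[1], params$gap_dur_range[2])
        start <- runif(1, 0, max(t_end - dur, 0.01))
        valid[tg >= start & tg <= start + dur] <- FALSE
      }
    }
    gaze <- tibble::tibble(t = tg, gx = gdir[, 1], gy = gdir[, 2],
                           gz = gdir[, 3], valid = valid)

    # pass event for misses: last moment the ball is still in front of the racquet
    hand_z_at <- function(tt) swing_position(tt, plan)[, 3]
    t_grid <- seq(traj$t_bounce, min(t_end, traj$t_end), by = 0.001)
    ball_z <- ball_state_at(traj, t_grid)$position[, 3]
    ahead <- ball_z > hand_z_at(t_grid)
    t_pass <- if (any(ahead)) t_grid[max(which(ahead))] else NA_real_

    list(
      motion = motion, gaze = gaze, ball = traj,
      events = list(t_launch = 0, t_bounce = traj$t_bounce,
                    t_contact = t_contact, t_pass = t_pass,
                    intercepted = !is.na(t_contact)),
      truth = list(rom = rom, pitch_fix = pitch_fix, yaw_fix = yaw_fix,
                   v_peak = plan$v_peak_eff, tau = tau, belief = beh$belief,
                   effective_belief = b_eff,
                   fix_on = fix_on, fix_off = fix_off,
                   t_foreswing_on = plan$t_on, t_cross = plan$t_cross)
    )
  })
}
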
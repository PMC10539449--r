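#' Projectile-and-bounce physics for the racquetball task
#'
#' Balls are launched from a height of 2 m, fall under gravity
#' (-9.8 m/s^2), reach a vertical velocity of exactly -9 m/s at the moment
#' of floor contact 3.5 m in front of the participant's starting position,
#' and rebound with a vertical speed scaled by the coefficient of
#' restitution (0.65 for normal balls, 0.85 for bouncy ones). Horizontal
#' velocity is constant throughout (no drag or spin), so the two ball types
#' are indistinguishable until the bounce.
#'
#' World frame: origin at the participant's starting position on the floor,
#' +z toward the front wall, +y up, +x toward the dominant side. Angles in
#' degrees, SI units throughout.
#'
#' @name ball_physics
NULL

#' Launch specification with the task's default geometry
#'
#' The launch point sits on the front wall's plane (z = 9 m, the prescribed
#' distance between participant and wall) at 2 m height; the ball travels
#' 5.5 m horizontally to the bounce point at z = 3.5 m, offset 0.75 m toward
#' the dominant side. The vertical-velocity constraint (-9 m/s at the
#' bounce) admits two launch arcs; the slower, upward "serve" arc is the
#' default.
#'
#' @param launch_height m above the floor (2).
#' @param bounce_distance_from_start m in front of the start position (3.5).
#' @param lateral_offset m toward the dominant side (0.75).
#' @param participant_wall_distance m from start position to front wall (9).
#' @param vz_at_bounce vertical velocity at floor contact, m/s (-9).
#' @param gravity m/s^2 (-9.8).
#' @param elasticity coefficient of restitution in (0, 1].
#' @param arc `"upward"` (default) or `"downward"` launch root.
#' @return list of class `"launch_spec"`.
#' @export
launch_spec <- function(launch_height = 2, bounce_distance_from_start = 3.5,
                        lateral_offset = 0.75, participant_wall_distance = 9,
                        vz_at_bounce = -9, gravity = -9.8,
                        elasticity = 0.65, arc = c("upward", "downward")) {
  spec <- list(
    launch_height = launch_height,
    bounce_distance_from_start = bounce_distance_from_start,
    lateral_offset = lateral_offset,
    participant_wall_distance = participant_wall_distance,
    vz_at_bounce = vz_at_bounce,
    gravity = gravity,
    elasticity = elasticity,
    arc = match.arg(arc)
  )
  if (launch_height < 0) stop("launch_height must be >= 0")
  if (elasticity <= 0 || elasticity > 1) stop("elasticity must be in (0, 1]")
  if (vz_at_bounce^2 < 2 * abs(gravity) * launch_height) {
    stop("unsolvable launch: need vz_at_bounce^2 >= 2*|gravity|*launch_height ",
         "for a real launch velocity")
  }
  structure(spec, class = "launch_spec")
}

#' Solve the launch state satisfying the bounce constraints
#'
#' Closed-form projectile solution: the vertical launch speed follows from
#' `v^2 = v0^2 + 2 g dh` between launch height and the floor, the flight
#' time from the linear velocity profile, and the horizontal speed from the
#' distance to the bounce point. The upward arc takes the positive vertical
#' root (launch speed about +6.47 m/s, flight about 1.58 s with defaults);
#' the downward root is exposed for completeness.
#'
#' @param spec a [launch_spec()].
#' @return list with `launch_point` (xyz, m), `launch_velocity` (xyz, m/s)
#'   and `flight_time` (s, launch to bounce).
#' @export
solve_launch <- function(spec) {
  g <- spec$gravity
  vb <- spec$vz_at_bounce
  vy0_sq <- vb^2 + 2 * g * spec$launch_height
  if (vy0_sq < 0) stop("unsolvable launch: vz_at_bounce^2 + 2*g*h < 0")
  vy0 <- if (spec$arc == "upward") sqrt(vy0_sq) else -sqrt(vy0_sq)
  flight_time <- (vb - vy0) / g
  launch_point <- c(spec$lateral_offset, spec$launch_height,
                    spec$participant_wall_distance)
  bounce_z <- spec$bounce_distance_from_start
  vz_horiz <- (bounce_z - spec$participant_wall_distance) / flight_time
  list(
    launch_point = launch_point,
    launch_velocity = c(0, vy0, vz_horiz),
    flight_time = flight_time
  )
}

#' Simulate a ball trajectory
#'
#' Piecewise-ballistic flight: free fall from the launch point to the floor,
#' an instantaneous bounce that scales the vertical speed by the elasticity
#' and leaves horizontal velocity unchanged, then free flight continuing
#' past the participant's depth plane. The bounce time is the exact
#' analytic root, never snapped to the sample grid; samples are a
#' convenience rendering of the analytic state.
#'
#' @param spec a [launch_spec()].
#' @param sample_rate Hz (default 120, the gaze clock).
#' @param end_z depth (m) past which simulation stops (default -1, one metre
#'   behind the participant); capped at a second floor contact if earlier.
#' @return list of class `"ball_trajectory"` with `samples` (tibble: t, x, y,
#'   z), `t_launch`, `t_bounce`, `t_end`, `bounce_point`, `post_bounce_apex`,
#'   the launch state and `spec`.
#' @export
simulate_trajectory <- function(spec, sample_rate = 120, end_z = -1) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  ls <- solve_launch(spec)
  g <- spec$gravity
  t_bounce <- ls$flight_time
  v_pre <- ls$launch_velocity + c(0, g * t_bounce, 0)
  vy_post <- spec$elasticity * abs(v_pre[2])
  bounce_point <- c(spec$lateral_offset, 0, spec$bounce_distance_from_start)
  # end: depth plane crossing or second floor contact, whichever is earlier
  vz <- ls$launch_velocity[3]
  t_depth <- t_bounce + (end_z - bounce_point[3]) / vz
  t_floor2 <- t_bounce + 2 * vy_post / abs(g)
  t_end <- min(t_depth, t_floor2)
  traj <- structure(
    list(t_launch = 0, t_bounce = t_bounce, t_end = t_end,
         launch_point = ls$launch_point,
         launch_velocity = ls$launch_velocity,
         v_pre_bounce = v_pre,
         v_post_bounce = c(v_pre[1], vy_post, v_pre[3]),
         bounce_point = bounce_point,
         post_bounce_apex = vy_post^2 / (2 * abs(g)),
         spec = spec),
    class = "ball_trajectory"
  )
  t <- seq(0, t_end, by = 1 / sample_rate)
  st <- ball_state_at(traj, t)
  traj$samples <- tibble::tibble(t = t, x = st$position[, 1],
                                 y = st$position[, 2], z = st$position[, 3])
  traj
}

#' Analytic ball state at a time point
#'
#' Exact piecewise-ballistic position and velocity; nothing is interpolated
#' from the sample grid. At the bounce instant itself the post-bounce state
#' is returned unless `side = "pre"`.
#'
#' @param traj a `"ball_trajectory"`.
#' @param t time(s) in seconds since launch; must lie within the simulated span.
#' @param side `"auto"` (post-bounce at the exact bounce time), `"pre"` or
#'   `"post"` to force the one-sided state at `t == t_bounce`.
#' @return list with `position` and `velocity`; matrices with one row per
#'   time point (vectors if `t` is scalar).
#' @export
ball_state_at <- function(traj, t, side = c("auto", "pre", "post")) {
  side <- match.arg(side)
  if (any(t < traj$t_launch - 1e-12) || any(t > traj$t_end + 1e-12)) {
    stop("t outside simulated span [", traj$t_launch, ", ", traj$t_end, "]")
  }
  g <- traj$spec$gravity
  pre <- t < traj$t_bounce | (t == traj$t_bounce & side == "pre")
  n <- length(t)
  pos <- matrix(0, n, 3)
  vel <- matrix(0, n, 3)
  # pre-bounce: ballistic from launch point
  tp <- t[pre]
  if (length(tp)) {
    p0 <- traj$launch_point; v0 <- traj$launch_velocity
    pos[pre, ] <- cbind(p0[1] + v0[1] * tp,
                        p0[2] + v0[2] * tp + 0.5 * g * tp^2,
                        p0[3] + v0[3] * tp)
    vel[pre, ] <- cbind(rep(v0[1], length(tp)), v0[2] + g * tp, rep(v0[3], length(tp)))
  }
  tq <- t[!pre] - traj$t_bounce
  if (length(tq)) {
    p0 <- traj$bounce_point; v0 <- traj$v_post_bounce
    pos[!pre, ] <- cbind(p0[1] + v0[1] * tq,
                         p0[2] + v0[2] * tq + 0.5 * g * tq^2,
                         p0[3] + v0[3] * tq)
    vel[!pre, ] <- cbind(rep(v0[1], length(tq)), v0[2] + g * tq, rep(v0[3], length(tq)))
  }
  if (n == 1) list(position = pos[1, ], velocity = vel[1, ])
  else list(position = pos, velocity = vel)
}

#' Time at which the ball crosses a given depth plane (post-bounce)
#'
#' @param traj a `"ball_trajectory"`.
#' @param z depth of the plane in metres.
#' @return time in seconds since launch.
#' @export
ball_crossing_time <- function(traj, z) {
  vz <- traj$v_post_bounce[3]
  t <- traj$t_bounce + (z - traj$bounce_point[3]) / vz
  if (t < traj$t_bounce || t > traj$t_end + 1e-9) {
    stop("plane z = ", z, " is not crossed after the bounce within the simulated span")
  }
  t
}

#' @export
print.ball_trajectory <- function(x, ...) {
  cat(sprintf("<ball_trajectory: e=%.2f, bounce at %.4f s, apex %.4f m, span %.3f s>\n",
              x$spec$elasticity, x$t_bounce, x$post_bounce_apex, x$t_end))
  invisible(x)
}
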
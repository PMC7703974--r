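# Failure kinematics: point-vehicle trajectories under a constant yaw-rate
# bias on a straight-plus-constant-curvature road, and time-to-lane-crossing.

#' Road geometry for a takeover trial
#'
#' Describes the track used in the takeover experiment: a straight lead-in
#' section joined to a constant-curvature bend. A straight road (no bend) is
#' represented by `bend_radius = Inf`.
#'
#' @param straight_length Length of the straight lead-in section in metres.
#' @param bend_radius Radius of the bend in metres; `Inf` for a straight road.
#' @param bend_direction `"left"` or `"right"`.
#' @param road_width Width of the road in metres; the vehicle (a point) leaves
#'   the road when its unsigned lateral offset reaches `road_width / 2`.
#' @param speed Constant vehicle speed in metres/second.
#'
#' @details Defaults describe the simulator track: a 16 m (2 s) straight
#'   section followed by an 80 m-radius bend, 3 m road width, at a constant
#'   8 m/s.
#'
#' @return An object of class `"road_geometry"`.
#' @export
#' @examples
#' road_geometry()
#' road_geometry(bend_radius = 500, road_width = 3.65, speed = mph_to_ms(60))
road_geometry <- function(straight_length = 16, bend_radius = 80,
                          bend_direction = c("left", "right"),
                          road_width = 3, speed = 8) {
  bend_direction <- match.arg(bend_direction)
  if (!is.numeric(bend_radius) || length(bend_radius) != 1 || bend_radius <= 0)
    stop("`bend_radius` must be a single positive number (Inf for a straight road)")
  if (!is.numeric(road_width) || road_width <= 0) stop("`road_width` must be > 0")
  if (!is.numeric(speed) || speed <= 0) stop("`speed` must be > 0")
  if (!is.numeric(straight_length) || straight_length < 0)
    stop("`straight_length` must be >= 0")
  structure(list(straight_length = straight_length, bend_radius = bend_radius,
                 bend_direction = bend_direction, road_width = road_width,
                 speed = speed),
            class = "road_geometry")
}

#' @export
print.road_geometry <- function(x, ...) {
  bend <- if (is.infinite(x$bend_radius)) "straight road" else
    sprintf("%g m %s bend", x$bend_radius, x$bend_direction)
  cat(sprintf("Road geometry: %g m straight + %s, width %g m, speed %g m/s\n",
              x$straight_length, bend, x$road_width, x$speed))
  invisible(x)
}

#' Convert miles per hour to metres per second
#'
#' @param mph Speed in miles per hour.
#' @return Speed in metres per second.
#' @export
#' @examples
#' mph_to_ms(60) # 26.82
mph_to_ms <- function(mph) mph * 0.44704

#' Tangential yaw-rate offset
#'
#' The yaw-rate offset that exactly cancels the curvature-following yaw rate
#' `speed / bend_radius`, so that the vehicle continues along its longitudinal
#' axis (an "off-tangent" failure). On a straight road the offset is zero.
#'
#' @param speed Vehicle speed in m/s.
#' @param bend_radius Bend radius in metres (`Inf` for a straight road).
#' @return Yaw-rate offset magnitude in degrees/second.
#' @export
#' @examples
#' tangential_offset(8, 80)      # 5.73 deg/s
#' tangential_offset(26.82, 500) # 3.07 deg/s
tangential_offset <- function(speed, bend_radius) {
  if (any(speed <= 0)) stop("`speed` must be > 0")
  if (any(bend_radius <= 0)) stop("`bend_radius` must be > 0 (Inf for straight)")
  ifelse(is.infinite(bend_radius), 0, speed / bend_radius * 180 / pi)
}

#' Smooth-step ramp weight
#'
#' C1-continuous ramp from 0 to 1 used to introduce the yaw-rate bias without
#' a detectable jerk: the quintic "smootherstep" polynomial
#' \eqn{6u^5 - 15u^4 + 10u^3}, which has zero first and second derivatives at
#' both ends of the ramp. Values outside the ramp are clamped.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param onset Ramp start time in seconds.
#' @param duration Ramp duration in seconds (default 0.5).
#' @return Weight(s) in `[0, 1]`.
#' @export
smooth_step <- function(t, onset, duration = 0.5) {
  if (duration <= 0) stop("`duration` must be > 0")
  u <- pmin(pmax((t - onset) / duration, 0), 1)
  u * u * u * (u * (6 * u - 15) + 10)
}

#' Silent failure specification
#'
#' One silent-failure condition: the criticality `tlc_f` (time-to-lane-crossing
#' from failure onset in the absence of a response), the onset time, the
#' yaw-rate offset magnitude, the drift direction, and an index into the pool
#' of pre-recorded automation trajectories.
#'
#' @param tlc_f Failure criticality in seconds (> 0).
#' @param onset Failure onset in seconds into the trial (>= 0).
#' @param yaw_offset Yaw-rate offset magnitude in degrees/second (>= 0); the
#'   `direction` carries the sign.
#' @param direction `"understeer"` (drift towards the outside of the bend) or
#'   `"oversteer"` (towards the inside).
#' @param trajectory_id Index into the automation-trajectory pool.
#' @return An object of class `"failure_spec"`.
#' @export
failure_spec <- function(tlc_f, onset = 6, yaw_offset = NA_real_,
                         direction = c("understeer", "oversteer"),
                         trajectory_id = 1L) {
  direction <- match.arg(direction)
  if (!is.na(tlc_f) && tlc_f <= 0) stop("`tlc_f` must be > 0")
  if (onset < 0) stop("`onset` must be >= 0")
  if (!is.na(yaw_offset) && yaw_offset < 0)
    stop("`yaw_offset` must be >= 0; `direction` carries the sign")
  structure(list(tlc_f = tlc_f, onset = onset, yaw_offset = yaw_offset,
                 direction = direction, trajectory_id = as.integer(trajectory_id)),
            class = "failure_spec")
}

# Signed yaw-rate offset in rad/s. Understeer reduces the curvature-following
# rate (drift to the outside of the bend); oversteer increases it. On a
# straight road "understeer" maps to a negative lateral drift by convention.
signed_yaw_offset <- function(yaw_offset_degps, direction, geom) {
  turn <- if (is.infinite(geom$bend_radius)) 1 else
    if (geom$bend_direction == "left") 1 else -1
  s <- if (direction == "understeer") -1 else 1
  s * turn * yaw_offset_degps * pi / 180
}

# Nominal (curvature-following) yaw rate at trial time t, rad/s. The
# automation follows the centreline on schedule: straight until the lead-in
# arc is covered, then the bend rate.
nominal_yaw_rate <- function(t, geom) {
  turn <- if (is.infinite(geom$bend_radius)) 0 else
    if (geom$bend_direction == "left") 1 else -1
  on_bend <- t * geom$speed >= geom$straight_length
  ifelse(on_bend, turn * geom$speed / geom$bend_radius, 0)
}

# Signed lateral offset of point (x, y) from the road centreline.
# Convention: positive = inside of the bend (the oversteer side), negative =
# outside (understeer), matching lane-position plots where negative values
# correspond to understeering. On the straight section the sign is chosen so
# that an understeer drift is negative.
lateral_offset_xy <- function(x, y, t, geom) {
  on_bend <- t * geom$speed >= geom$straight_length
  if (is.infinite(geom$bend_radius)) return(y)
  turn <- if (geom$bend_direction == "left") 1 else -1
  cx <- geom$straight_length
  cy <- turn * geom$bend_radius
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  ifelse(on_bend, geom$bend_radius - r, turn * y)
}

#' Simulate a silent-failure trajectory
#'
#' Integrates a point-vehicle trajectory at constant speed whose yaw rate is
#' the nominal curvature-following rate plus the signed yaw-rate offset of the
#' failure, ramped in with [smooth_step()]. Each integration step treats the
#' yaw rate as constant over the step and advances the position along the
#' corresponding circular arc (exact for piecewise-constant yaw rate), at the
#' simulator's 60 Hz record rate by default.
#'
#' @param spec A [failure_spec()]; `spec$yaw_offset` must be set.
#' @param geom A [road_geometry()].
#' @param dt Integration step in seconds (default 1/60).
#' @param horizon Simulation length in seconds (must cover `spec$onset`).
#' @param ramp_duration Yaw-offset ramp duration in seconds (default 0.5;
#'   use 0 for an instantaneous failure).
#' @return A data frame of class `"failure_trajectory"` with columns `time`,
#'   `x`, `y`, `heading` (rad), `yaw_rate` (rad/s), `lateral_offset` (m,
#'   signed: negative = understeer side) and `heading_error` (rad, relative to
#'   the road tangent, wrapped to (-pi, pi]).
#' @export
simulate_failure <- function(spec, geom, dt = 1 / 60, horizon = 30,
                             ramp_duration = 0.5) {
  stopifnot(inherits(spec, "failure_spec"), inherits(geom, "road_geometry"))
  if (dt <= 0) stop("`dt` must be > 0")
  if (horizon < spec$onset) stop("`horizon` must cover the failure onset")
  if (is.na(spec$yaw_offset)) stop("`spec$yaw_offset` is not set")

  n <- ceiling(horizon / dt) + 1L
  tgrid <- (seq_len(n) - 1L) * dt
  off <- signed_yaw_offset(spec$yaw_offset, spec$direction, geom)
  w <- if (ramp_duration > 0)
    smooth_step(tgrid + dt / 2, spec$onset, ramp_duration)
  else as.numeric(tgrid + dt / 2 >= spec$onset)
  omega <- nominal_yaw_rate(tgrid + dt / 2, geom) + off * w

  x <- y <- heading <- numeric(n)
  th <- 0
  px <- 0; py <- 0
  v <- geom$speed
  for (i in seq_len(n - 1L)) {
    om <- omega[i]
    if (abs(om) < 1e-12) {
      px <- px + v * dt * cos(th)
      py <- py + v * dt * sin(th)
    } else {
      th2 <- th + om * dt
      px <- px + v / om * (sin(th2) - sin(th))
      py <- py - v / om * (cos(th2) - cos(th))
      th <- th2
    }
    x[i + 1L] <- px; y[i + 1L] <- py; heading[i + 1L] <- th
  }

  lat <- lateral_offset_xy(x, y, tgrid, geom)
  tangent <- road_tangent(tgrid, x, y, geom)
  herr <- wrap_angle(heading - tangent)
  out <- data.frame(time = tgrid, x = x, y = y, heading = heading,
                    yaw_rate = c(omega[-n], omega[n]),
                    lateral_offset = lat, heading_error = herr)
  class(out) <- c("failure_trajectory", "data.frame")
  attr(out, "geometry") <- geom
  attr(out, "spec") <- spec
  out
}

# Road-tangent heading at the centreline point nearest (by schedule) to the
# vehicle: straight-section tangent before the bend entry, bend tangent after.
road_tangent <- function(t, x, y, geom) {
  if (is.infinite(geom$bend_radius)) return(rep(0, length(t)))
  turn <- if (geom$bend_direction == "left") 1 else -1
  on_bend <- t * geom$speed >= geom$straight_length
  cx <- geom$straight_length
  cy <- turn * geom$bend_radius
  ang <- atan2(y - cy, x - cx)
  ifelse(on_bend, ang + turn * pi / 2, 0)
}

wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  ifelse(out <= -pi, out + 2 * pi, out)
}

#' Time to lane crossing
#'
#' First time at or after `from_time` at which the unsigned lateral offset
#' reaches half the road width (either edge), minus `from_time`. The crossing
#' instant is linearly interpolated between trajectory samples. If the
#' trajectory never leaves the lane within its horizon, `Inf` is returned
#' (a no-crossing sentinel, not an error).
#'
#' @param traj A `"failure_trajectory"` from [simulate_failure()].
#' @param geom A [road_geometry()]; defaults to the trajectory's own geometry.
#' @param from_time Reference time in seconds (e.g. the failure onset).
#' @return Time to lane crossing in seconds, or `Inf` if no crossing occurs.
#' @export
time_to_lane_crossing <- function(traj, geom = attr(traj, "geometry"),
                                  from_time = 0) {
  stopifnot(inherits(traj, "failure_trajectory"))
  half <- geom$road_width / 2
  keep <- traj$time >= from_time
  tt <- traj$time[keep]
  la <- abs(traj$lateral_offset[keep])
  idx <- which(la >= half)
  if (!length(idx)) return(Inf)
  i <- idx[1L]
  if (i == 1L) return(tt[1L] - from_time)
  # linear interpolation between the bracketing samples
  frac <- (half - la[i - 1L]) / (la[i] - la[i - 1L])
  tt[i - 1L] + frac * (tt[i] - tt[i - 1L]) - from_time
}

#' Solve the yaw-rate offset for a target criticality
#'
#' Inverse design: finds the yaw-rate offset magnitude whose simulated failure
#' (from the road centreline, zero heading error) has a time-to-lane-crossing
#' equal to `target_tlc_f`. Solved by bisection on the offset; the
#' time-to-lane-crossing is monotone non-increasing in the offset magnitude.
#'
#' @param target_tlc_f Target criticality in seconds.
#' @param geom A [road_geometry()].
#' @param onset Failure onset in seconds (default 6).
#' @param direction Drift direction, `"understeer"` or `"oversteer"`.
#' @param max_offset Upper bracket for the offset in deg/s; defaults to four
#'   times the tangential offset (or 20 deg/s on a straight road).
#' @param tol Bisection tolerance on the offset in deg/s (default 1e-4).
#' @param dt,ramp_duration Passed to [simulate_failure()].
#' @return Yaw-rate offset magnitude in degrees/second.
#' @export
solve_offset_for_tlc <- function(target_tlc_f, geom, onset = 6,
                                 direction = c("understeer", "oversteer"),
                                 max_offset = NULL, tol = 1e-4,
                                 dt = 1 / 60, ramp_duration = 0.5) {
  direction <- match.arg(direction)
  if (target_tlc_f <= 0) stop("`target_tlc_f` must be > 0")
  tang <- tangential_offset(geom$speed, geom$bend_radius)
  if (is.null(max_offset)) max_offset <- if (tang > 0) 4 * tang else 20
  horizon <- onset + max(2 * target_tlc_f, 10)

  tlc_at <- function(off) {
    sp <- failure_spec(tlc_f = target_tlc_f, onset = onset, yaw_offset = off,
                       direction = direction)
    tr <- simulate_failure(sp, geom, dt = dt, horizon = horizon,
                           ramp_duration = ramp_duration)
    time_to_lane_crossing(tr, geom, from_time = onset)
  }

  hi <- max_offset
  tlc_hi <- tlc_at(hi)
  if (target_tlc_f < tlc_hi)
    stop(sprintf(paste0("target TLC_F %.3f s is not achievable: the fastest ",
                        "crossing within the offset bracket is %.3f s"),
                 target_tlc_f, tlc_hi))
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    tlc_mid <- tlc_at(mid)
    if (tlc_mid > target_tlc_f) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Criticality threshold at trial end
#'
#' The time-to-lane-crossing value at the end of the trial. Takeovers slower
#' than this cannot be observed: the trial ends first, and the response is
#' censored. May be negative, in which case the vehicle leaves the road well
#' before trial end and censoring never binds.
#'
#' @param tlc_f Failure criticality in seconds.
#' @param onset Failure onset in seconds into the trial.
#' @param trial_length Trial length in seconds (>= `onset`).
#' @return `tlc_f - (trial_length - onset)`, in seconds.
#' @export
#' @examples
#' tlc_end(9.55, 6, 15) # 0.55
#' tlc_end(2.23, 6, 15) # -6.77
tlc_end <- function(tlc_f, onset, trial_length) {
  if (any(trial_length < onset)) stop("`trial_length` must be >= `onset`")
  tlc_f - (trial_length - onset)
}

#' Criticality of an off-tangent failure in a road scenario
#'
#' Time-to-lane-crossing for a vehicle that stops turning and travels straight
#' ahead (a tangential failure) from the centre of its lane on a bend of the
#' given radius, with zero heading error. Used to place real-world road
#' designs on the failure-criticality axis of a risk curve.
#'
#' @param radius Bend radius in metres (`Inf` returns `Inf`: no crossing).
#' @param speed Vehicle speed, in the unit named by `speed_unit`.
#' @param lane_width Lane width in metres.
#' @param speed_unit `"ms"` (metres/second) or `"mph"`; required so that the
#'   speed is never ambiguous.
#' @param dt Integration step in seconds (default 1/240 for a sharp estimate).
#' @return Time-to-lane-crossing in seconds.
#' @export
#' @examples
#' scenario_tlc(500, 60, 3.65, "mph")  # about 1.6 s (rural single carriageway)
#' scenario_tlc(2000, 70, 3.65, "mph") # about 2.7 s (motorway)
scenario_tlc <- function(radius, speed, lane_width, speed_unit = c("ms", "mph"),
                         dt = 1 / 240) {
  speed_unit <- match.arg(speed_unit)
  v <- if (speed_unit == "mph") mph_to_ms(speed) else speed
  if (radius <= 0 || v <= 0 || lane_width <= 0)
    stop("`radius`, `speed` and `lane_width` must be positive")
  if (is.infinite(radius)) return(Inf)
  geom <- road_geometry(straight_length = 0, bend_radius = radius,
                        road_width = lane_width, speed = v)
  sp <- failure_spec(tlc_f = 1, onset = 0,
                     yaw_offset = tangential_offset(v, radius),
                     direction = "understeer")
  horizon <- 2 * sqrt(2 * radius * lane_width / 2) / v + 5
  tr <- simulate_failure(sp, geom, dt = dt, horizon = horizon,
                         ramp_duration = 0)
  time_to_lane_crossing(tr, geom, from_time = 0)
}
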
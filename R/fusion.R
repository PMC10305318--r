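# Orientation, altitude, and feature-stream computation.
#
# Quaternions are (w, x, y, z), body-to-earth convention. Device frame:
# +X wearer's right, +Y anterior, +Z superior; earth frame +Z up. The
# gravity direction expressed in the body frame is the third row of the
# body-to-earth rotation matrix and is what both the orientation filter and
# the lean-angle extraction work from.
#
# Lean-angle conventions (matching how fall direction is read off the
# device): forward lean -> pitch > 0, right lean -> roll > 0, both zero at
# upright stance.

.deg <- 180 / pi

#' Resultant G value
#'
#' Euclidean norm of the three acceleration axes: the "sum vector magnitude"
#' used throughout the pipeline. Approximately 1 g at rest, dips toward 0
#' during the weightless phase of a fall, and spikes at ground impact. The
#' result carries the unit of its input (g or raw counts).
#'
#' @param acc numeric length-3 vector, or an n-by-3 matrix/data frame of
#'   samples.
#' @return scalar, or length-n vector for matrix input.
#' @export
#' @examples
#' g_value(c(3, 4, 0))   # 5
g_value <- function(acc) {
  if (is.data.frame(acc)) acc <- as.matrix(acc)
  if (is.matrix(acc)) {
    stopifnot(ncol(acc) == 3)
    if (!all(is.finite(acc))) stop("non-finite acceleration input")
    return(sqrt(rowSums(acc^2)))
  }
  stopifnot(length(acc) == 3)
  if (!all(is.finite(acc))) stop("non-finite acceleration input")
  sqrt(sum(acc^2))
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg / .deg / 2
  c(cos(h), sin(h) * axis)
}

# Gravity direction (earth up) in body coordinates: third row of the
# body-to-earth rotation matrix.
quat_up_in_body <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

#' Orientation state for the gradient-descent filter
#'
#' @param q unit quaternion (w, x, y, z), body-to-earth; default identity
#'   (device upright).
#' @param beta gradient gain of the filter (dimensionless). 0.1 is the
#'   customary value at 100 Hz: large enough to pull integration drift back
#'   to the accelerometer vertical within seconds, small enough not to chase
#'   transient linear accelerations.
#' @return object of class `orientation_state` with fields `q`, `roll`,
#'   `pitch`, `yaw` (degrees) and `beta`.
#' @export
orientation_state <- function(q = c(1, 0, 0, 0), beta = 0.1) {
  q <- quat_normalize(q)
  e <- quaternion_to_euler(q)
  structure(list(q = q, roll = e[["roll"]], pitch = e[["pitch"]],
                 yaw = e[["yaw"]], beta = beta, gyro_only = FALSE),
            class = "orientation_state")
}

#' Quaternion to lean angles
#'
#' Decomposes a body-to-earth quaternion as yaw about earth Z, then pitch
#' about the body lateral axis, then roll about the body anterior axis
#' (a Z-X-Y sequence), with signs chosen so a forward lean gives positive
#' pitch and a right lean gives positive roll. The identity quaternion maps
#' to (0, 0, 0). Within 0.1 degree of the gimbal singularity
#' (|pitch| > 89.9) the pitch is clamped and the result carries a
#' `gimbal` attribute.
#'
#' @param q unit quaternion (w, x, y, z).
#' @return named numeric vector `c(roll, pitch, yaw)` in degrees, each in
#'   (-180, 180].
#' @export
quaternion_to_euler <- function(q) {
  stopifnot(length(q) == 4, abs(sqrt(sum(q^2)) - 1) < 1e-6)
  v <- quat_up_in_body(q)
  s <- min(1, max(-1, v[2]))
  pitch <- -asin(s) * .deg
  gimbal <- abs(pitch) > 89.9
  if (gimbal) pitch <- sign(pitch) * 89.9
  roll <- atan2(-v[1], v[3]) * .deg
  # body anterior axis expressed in earth frame: second column of R
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  fx <- 2 * (x * y - w * z)
  fy <- 1 - 2 * (x^2 + z^2)
  yaw <- atan2(-fx, fy) * .deg
  out <- c(roll = roll, pitch = pitch, yaw = yaw)
  if (gimbal) attr(out, "gimbal") <- TRUE
  out
}

#' Lean angles to quaternion
#'
#' Inverse of [quaternion_to_euler()] away from the gimbal singularity.
#'
#' @param roll,pitch,yaw degrees.
#' @return unit quaternion (w, x, y, z).
#' @export
euler_to_quaternion <- function(roll, pitch, yaw = 0) {
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  qx <- quat_from_axis_angle(c(1, 0, 0), -pitch)
  qy <- quat_from_axis_angle(c(0, 1, 0), roll)
  quat_normalize(quat_multiply(quat_multiply(qz, qx), qy))
}

#' One gradient-descent orientation update
#'
#' Advances the orientation quaternion by one sample: the quaternion rate
#' from gyroscope integration, minus `beta` times the normalized gradient of
#' the accelerometer (and, when a magnetic field is present, magnetometer)
#' objective function, then Euler integration over `dt` and renormalization.
#' A zero-norm accelerometer vector degrades the step to gyro-only
#' integration and flags the state (`gyro_only`).
#'
#' @param state an [orientation_state()].
#' @param sample either a named list/row with fields `gx, gy, gz` (deg/s),
#'   `ax, ay, az` (g) and optionally `mx, my, mz` (uT), or a list with
#'   elements `acc`, `gyro`, `mag`.
#' @param dt time step in seconds (> 0).
#' @return the updated `orientation_state`.
#' @export
madgwick_update <- function(state, sample, dt) {
  stopifnot(inherits(state, "orientation_state"), dt > 0)
  if (!is.null(sample$acc)) {
    acc <- as.numeric(sample$acc); gyr <- as.numeric(sample$gyro)
    mag <- if (!is.null(sample$mag)) as.numeric(sample$mag) else NULL
  } else {
    acc <- as.numeric(c(sample$ax, sample$ay, sample$az))
    gyr <- as.numeric(c(sample$gx, sample$gy, sample$gz))
    mag <- if (!is.null(sample$mx))
      as.numeric(c(sample$mx, sample$my, sample$mz)) else NULL
  }
  res <- madgwick_step_cpp(state$q, acc, gyr / .deg,
                           if (is.null(mag)) numeric(0) else mag,
                           dt, state$beta)
  out <- orientation_state(res$q, beta = state$beta)
  out$gyro_only <- res$gyro_only
  out
}

#' Run the orientation filter over a whole trace
#'
#' Batch version of [madgwick_update()] over every sample of a log, with the
#' loop in compiled code. The magnetometer branch is used automatically when
#' the log carries `mx, my, mz` columns.
#'
#' @param log a [sensor_log()].
#' @param beta gradient gain.
#' @param q0 initial quaternion (default identity).
#' @return data frame with one row per sample: `t`, quaternion columns
#'   `qw, qx, qy, qz`, and `roll, pitch, yaw` in degrees.
#' @export
madgwick_filter <- function(log, beta = 0.1, q0 = c(1, 0, 0, 0)) {
  stopifnot(nrow(log) > 0)
  dt <- diff(log$t)
  dt <- c(if (length(dt)) stats::median(dt) else 1 / attr(log, "rate_hz"), dt)
  acc <- as.matrix(log[, c("ax", "ay", "az")])
  gyr <- as.matrix(log[, c("gx", "gy", "gz")]) / .deg
  mag <- if (has_mag(log)) as.matrix(log[, c("mx", "my", "mz")]) else
    matrix(numeric(0), 0, 3)
  q <- madgwick_filter_cpp(acc, gyr, mag, dt, beta, quat_normalize(q0))
  eul <- t(apply(q, 1, quaternion_to_euler))
  data.frame(t = log$t, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             roll = eul[, 1], pitch = eul[, 2], yaw = eul[, 3])
}

#' Barometric pressure to relative altitude
#'
#' Hypsometric conversion under the standard atmosphere (sea-level
#' temperature 288.15 K, lapse rate 6.5 K/km): altitude relative to the
#' reference pressure `p_ref`, about +1 m per -12 Pa near sea level.
#'
#' @param p pressure in Pa (vectorized).
#' @param p_ref reference pressure in Pa (altitude 0).
#' @return altitude in metres relative to the reference level.
#' @export
#' @examples
#' pressure_to_altitude(101313, 101325)  # ~ +1 m
pressure_to_altitude <- function(p, p_ref) {
  rng <- .sensor_spec$pressure_range_pa
  if (any(p < rng[1] | p > rng[2]) || p_ref < rng[1] || p_ref > rng[2])
    stop("pressure outside barometer operating range")
  k <- 0.1902663  # R * L / (g0 * M) for the standard atmosphere
  (288.15 / 0.0065) * (1 - (p / p_ref)^k)
}

#' Relative altitude back to pressure
#'
#' Inverse of [pressure_to_altitude()].
#'
#' @param h altitude in metres relative to the reference level (vectorized).
#' @param p_ref reference pressure in Pa.
#' @return pressure in Pa.
#' @export
altitude_to_pressure <- function(h, p_ref) {
  k <- 0.1902663
  p_ref * (1 - h * 0.0065 / 288.15)^(1 / k)
}

#' Altitude Kalman filter state
#'
#' Scalar random-walk Kalman filter over the barometric relative altitude.
#'
#' @param altitude initial altitude estimate (m).
#' @param variance initial estimate variance (m^2).
#' @param p_ref reference pressure (Pa) fixing the zero level.
#' @param q_proc process noise per step (m^2).
#' @param r_meas measurement noise (m^2); the default matches the
#'   altitude-equivalent variance of a 6 Pa barometer noise floor.
#' @return object of class `altitude_state`.
#' @export
altitude_state <- function(altitude = 0, variance = 1, p_ref = 101325,
                           q_proc = 1e-4, r_meas = 0.25) {
  stopifnot(variance > 0, q_proc > 0, r_meas > 0)
  structure(list(altitude = altitude, variance = variance, p_ref = p_ref,
                 q_proc = q_proc, r_meas = r_meas, skipped = FALSE),
            class = "altitude_state")
}

#' One scalar Kalman predict-update step
#'
#' Random-walk predict (variance grows by `q_proc`) followed by a
#' measurement update with gain `K = P / (P + r_meas)`; the posterior
#' estimate is a convex combination of prior and measurement. A non-finite
#' measurement skips the update and flags the state.
#'
#' @param state an [altitude_state()].
#' @param z measured relative altitude (m), e.g. from
#'   [pressure_to_altitude()].
#' @return the updated `altitude_state`.
#' @export
kalman_altitude_update <- function(state, z) {
  stopifnot(inherits(state, "altitude_state"))
  if (!is.finite(z)) {
    state$skipped <- TRUE
    return(state)
  }
  state$skipped <- FALSE
  P <- state$variance + state$q_proc
  K <- P / (P + state$r_meas)
  state$altitude <- state$altitude + K * (z - state$altitude)
  state$variance <- (1 - K) * P
  state
}

#' Compute the feature streams for behavior and fall decisions
#'
#' Turns a raw trace into one feature frame per decision tick (default every
#' 0.1 s): instantaneous resultant G, fused roll/pitch/yaw, Kalman-filtered
#' relative altitude, the trailing-window pressure difference `dp_window`
#' (absolute change of the filtered barometric signal over 1.5 s, in Pa),
#' its signed altitude counterpart `dalt_window` (m), and `dg_window`, the
#' max-minus-min of the resultant G over the trailing 1 s (in g). Windows
#' that extend before the start of the trace are truncated and flagged.
#'
#' The pressure difference is evaluated on the Kalman-filtered altitude
#' mapped back through the hypsometric relation, not on raw samples: the
#' barometer noise floor (several Pa) would otherwise swamp the 3 Pa
#' decision threshold.
#'
#' @param log a [sensor_log()].
#' @param config a [fallsense_config()].
#' @return data frame of class `feature_frames` with columns `t, g_value,
#'   roll, pitch, yaw, altitude, dp_window, dalt_window, dg_window,
#'   truncated`; attribute `p_ref` records the reference pressure (median of
#'   the first half second).
#' @export
compute_features <- function(log, config = fallsense_config()) {
  stopifnot(nrow(log) > 1)
  fu <- config$fusion
  t <- log$t
  g <- g_value(log[, c("ax", "ay", "az")])
  orient <- madgwick_filter(log, beta = fu$beta)
  p_ref <- stats::median(log$p[t <= t[1] + 0.5])
  z <- pressure_to_altitude(log$p, p_ref)
  kf <- kalman_filter_cpp(z, 0, 1, fu$kalman_q, fu$kalman_r)
  alt <- kf$estimate

  tick <- fu$decision_tick_s
  tt <- seq(t[1] + tick, max(t), by = tick)
  idx <- findInterval(tt, t)                 # sample at or before each tick
  i_g0 <- findInterval(tt - fu$dg_window_s, t) + 1L
  i_g0 <- pmax(i_g0, 1L)
  i_p0 <- findInterval(tt - fu$dp_window_s, t)
  truncated <- tt - fu$dp_window_s < t[1]
  i_p0 <- pmax(i_p0, 1L)

  n <- length(tt)
  dg <- vapply(seq_len(n), function(i) {
    w <- g[i_g0[i]:idx[i]]
    max(w) - min(w)
  }, numeric(1))
  dalt <- alt[idx] - alt[i_p0]
  p_now <- altitude_to_pressure(alt[idx], p_ref)
  p_then <- altitude_to_pressure(alt[i_p0], p_ref)
  out <- data.frame(
    t = tt,
    g_value = g[idx],
    roll = orient$roll[idx],
    pitch = orient$pitch[idx],
    yaw = orient$yaw[idx],
    altitude = alt[idx],
    dp_window = abs(p_now - p_then),
    dalt_window = dalt,
    dg_window = dg,
    truncated = truncated
  )
  attr(out, "p_ref") <- p_ref
  attr(out, "tick_s") <- tick
  class(out) <- c("feature_frames", "data.frame")
  out
}
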
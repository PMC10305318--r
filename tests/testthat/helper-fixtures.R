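# Fixtures are built in code: small noise-free traces with known kinematics.

# Quiet upright stance: accelerometer reads (0, 0, 1) g, constant pressure.
make_quiet_log <- function(duration = 10, rate = 100, p = 101325) {
  t <- seq(1 / rate, duration, by = 1 / rate)
  sensor_log(data.frame(t = t, ax = 0, ay = 0, az = 1,
                        gx = 0, gy = 0, gz = 0, p = p),
             rate_hz = rate, validate = FALSE)
}

# Static lean: gravity direction in the body frame for given lean angles
# (forward lean -> pitch > 0, right lean -> roll > 0), zero rates.
make_tilt_log <- function(roll = 0, pitch = 0, duration = 20, rate = 100) {
  a <- -pitch * pi / 180
  b <- roll * pi / 180
  v <- c(-sin(b) * cos(a), sin(a), cos(a) * cos(b))
  t <- seq(1 / rate, duration, by = 1 / rate)
  sensor_log(data.frame(t = t, ax = v[1], ay = v[2], az = v[3],
                        gx = 0, gy = 0, gz = 0, p = 101325),
             rate_hz = rate, validate = FALSE)
}

# Hand-built feature frames for direct detector/FSM unit tests.
make_frames <- function(t, g_value = 1, roll = 0, pitch = 0, yaw = 0,
                        altitude = 0, dp_window = 0, dalt_window = 0,
                        dg_window = 0) {
  f <- data.frame(t = t, g_value = g_value, roll = roll, pitch = pitch,
                  yaw = yaw, altitude = altitude, dp_window = dp_window,
                  dalt_window = dalt_window, dg_window = dg_window,
                  truncated = FALSE)
  attr(f, "tick_s") <- if (length(t) > 1) t[2] - t[1] else 0.1
  class(f) <- c("feature_frames", "data.frame")
  f
}
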
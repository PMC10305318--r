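test_that("resultant G is the Euclidean norm, unit-agnostic and symmetric", {
  expect_equal(g_value(c(0, 0, 512)), 512)
  expect_equal(g_value(c(3, 4, 0)), 5)
  expect_equal(g_value(c(300, 400, 1200)), 1300)
  expect_error(g_value(c(1, NA, 0)), "non-finite")
  # invariant under axis permutation and sign flips
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(3)
    expect_equal(g_value(sample(a)), g_value(a))
    expect_equal(g_value(a * sample(c(-1, 1), 3, TRUE)), g_value(a))
  }
})

test_that("euler conversion: identity, axis rotations, and round trips", {
  expect_equal(unname(quaternion_to_euler(c(1, 0, 0, 0))), c(0, 0, 0))
  q90 <- euler_to_quaternion(90, 0, 0)     # 90 deg right lean (roll axis)
  expect_equal(quaternion_to_euler(q90)[["roll"]], 90, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:50) {
    e <- c(roll = runif(1, -170, 170), pitch = runif(1, -85, 85),
           yaw = runif(1, -170, 170))
    back <- quaternion_to_euler(euler_to_quaternion(e[1], e[2], e[3]))
    expect_equal(unname(back), unname(e), tolerance = 1e-6)
  }
})

test_that("orientation filter holds the gravity-aligned equilibrium", {
  o <- madgwick_filter(make_quiet_log(5))
  expect_lt(abs(o$roll[nrow(o)]), 0.5)
  expect_lt(abs(o$pitch[nrow(o)]), 0.5)
})

test_that("static tilts converge to the accelerometer closed form", {
  # oracle: for a static accelerometer reading the lean angle is
  # atan2(horizontal component, vertical component)
  for (tilt in seq(-60, 60, by = 20)) {
    log <- make_tilt_log(pitch = tilt)
    oracle <- atan2(-log$ay[1], log$az[1]) * 180 / pi
    o <- madgwick_filter(log)
    expect_equal(o$pitch[nrow(o)], oracle, tolerance = 0.5)
    log <- make_tilt_log(roll = tilt)
    oracle <- atan2(-log$ax[1], log$az[1]) * 180 / pi
    o <- madgwick_filter(log)
    expect_equal(o$roll[nrow(o)], oracle, tolerance = 0.5)
  }
})

test_that("gyro-only integration recovers a 90 degree rotation", {
  t <- seq(0.01, 1, by = 0.01)
  log <- sensor_log(data.frame(t = t, ax = 0, ay = 0, az = 1,
                               gx = -90, gy = 0, gz = 0, p = 101325),
                    validate = FALSE)
  o <- madgwick_filter(log, beta = 0)   # pure integration
  expect_equal(o$pitch[nrow(o)], 90, tolerance = 1)
  log$gx <- 0; log$gy <- 90
  o <- madgwick_filter(log, beta = 0)
  expect_equal(o$roll[nrow(o)], 90, tolerance = 1)
})

test_that("quaternion norm is preserved to 1e-9 over 1e5 updates", {
  set.seed(42)
  n <- 1e5
  t <- seq_len(n) / 100
  log <- sensor_log(data.frame(t = t,
                               ax = rnorm(n, 0, 0.3), ay = rnorm(n, 0, 0.3),
                               az = rnorm(n, 1, 0.3), gx = rnorm(n, 0, 100),
                               gy = rnorm(n, 0, 100), gz = rnorm(n, 0, 100),
                               p = 101325), validate = FALSE)
  o <- madgwick_filter(log)
  norms <- sqrt(o$qw^2 + o$qx^2 + o$qy^2 + o$qz^2)
  expect_lt(max(abs(norms - 1)), 1e-9)
})

test_that("single-step updates agree with the batch filter", {
  set.seed(3)
  n <- 50
  df <- data.frame(t = seq_len(n) / 100,
                   ax = rnorm(n, 0, 0.1), ay = rnorm(n, 0, 0.1),
                   az = rnorm(n, 1, 0.1), gx = rnorm(n, 0, 30),
                   gy = rnorm(n, 0, 30), gz = rnorm(n, 0, 30), p = 101325)
  log <- sensor_log(df, validate = FALSE)
  batch <- madgwick_filter(log)
  st <- orientation_state()
  for (i in seq_len(n)) st <- madgwick_update(st, df[i, ], 0.01)
  expect_equal(st$q, unlist(batch[n, c("qw", "qx", "qy", "qz")],
                            use.names = FALSE), tolerance = 1e-12)
  # zero-norm accelerometer degrades to flagged gyro-only integration
  st2 <- madgwick_update(orientation_state(),
                         list(acc = c(0, 0, 0), gyro = c(10, 0, 0)), 0.01)
  expect_true(st2$gyro_only)
})

test_that("magnetometer branch keeps static convergence and unit norm", {
  t <- seq(0.01, 10, by = 0.01)
  log <- sensor_log(data.frame(t = t, ax = 0, ay = 0, az = 1,
                               gx = 0, gy = 0, gz = 0,
                               mx = 22, my = 1, mz = -43, p = 101325),
                    validate = FALSE)
  o <- madgwick_filter(log)
  expect_lt(abs(o$roll[nrow(o)]), 0.5)
  expect_lt(abs(o$pitch[nrow(o)]), 0.5)
  expect_lt(abs(sqrt(sum(o[nrow(o), c("qw", "qx", "qy", "qz")]^2)) - 1), 1e-9)
})

test_that("hypsometric conversion matches the 12 Pa-per-metre rule", {
  expect_equal(pressure_to_altitude(101325, 101325), 0)
  expect_equal(pressure_to_altitude(101313, 101325), 1, tolerance = 0.02)
  expect_equal(pressure_to_altitude(101337, 101325), -1, tolerance = 0.02)
  expect_error(pressure_to_altitude(20000, 101325), "operating range")
  # exact inverse
  h <- seq(-50, 50, by = 10)
  expect_equal(pressure_to_altitude(altitude_to_pressure(h, 101325), 101325),
               h, tolerance = 1e-9)
})

test_that("altitude Kalman filter: fixed point, convergence, convexity", {
  st <- altitude_state()
  for (i in 1:50) st <- kalman_altitude_update(st, 0)
  expect_equal(st$altitude, 0)

  st <- altitude_state()
  prev <- 0
  for (i in 1:100) {
    st0 <- st
    st <- kalman_altitude_update(st, 1)
    expect_gte(st$altitude, prev)         # monotone approach
    expect_lte(st$altitude, 1)
    # posterior is a convex combination of prior and measurement
    expect_gte(st$altitude, min(st0$altitude, 1) - 1e-12)
    expect_lte(st$altitude, max(st0$altitude, 1) + 1e-12)
    prev <- st$altitude
  }

  # steady state under noise: the stationary gain K* gives estimate sd
  # sigma_z * sqrt(K* / (2 - K*)); final error within 3 sd of truth
  q <- 1e-4; r <- 0.01
  Pstar <- (-q + sqrt(q^2 + 4 * q * r)) / 2
  Kstar <- (Pstar + q) / (Pstar + q + r)
  sd_est <- 0.1 * sqrt(Kstar / (2 - Kstar))
  set.seed(11)
  st <- altitude_state(q_proc = q, r_meas = r)
  for (z in rnorm(200, 0.5, 0.1)) st <- kalman_altitude_update(st, z)
  expect_lt(abs(st$altitude - 0.5), 3 * sd_est + 0.5 * exp(-200 * Kstar))

  st_skip <- kalman_altitude_update(altitude_state(altitude = 2), NaN)
  expect_true(st_skip$skipped)
  expect_equal(st_skip$altitude, 2)
})

test_that("feature frames: quiet trace, tick count, window truncation", {
  frames <- compute_features(make_quiet_log(10))
  expect_equal(nrow(frames), 99)          # 0.1 s ticks over (0.01, 10]
  expect_equal(frames$g_value, rep(1, 99))
  expect_lt(max(frames$dp_window), 1e-9)
  expect_lt(max(frames$dg_window), 1e-9)
  expect_true(all(frames$truncated == (frames$t - 1.5 < 0.01)))
})

test_that("a pressure step appears in dp_window at the right time", {
  log <- make_quiet_log(10)
  log$p[log$t > 5] <- 101325 - 15         # step of -15 Pa at t = 5
  frames <- compute_features(log)
  peak_t <- frames$t[which.max(frames$dp_window)]
  expect_gte(peak_t, 5)
  expect_lte(peak_t, 6.5)
  # Kalman smoothing attenuates the step slightly within the 1.5 s window
  expect_gt(max(frames$dp_window), 10)
  expect_lte(max(frames$dp_window), 15.5)
  # far from the step the window difference decays back to zero
  expect_lt(max(frames$dp_window[frames$t > 8.5]), 1)
})
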
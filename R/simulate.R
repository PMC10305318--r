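# Seeded synthetic sensor-trace generator.
#
# Each trial is a script of kinematic segments (quiet stance, walking in
# place, sitting down, standing up, deliberate lying, falls in four
# directions). A segment prescribes the true lean-angle trajectory
# (roll/pitch), the true chest altitude, and the resultant-acceleration
# magnitude profile; the sampled signals are derived from those:
# accelerometer = magnitude x (gravity direction in the body frame),
# gyroscope = exact body rates of the quaternion trajectory, barometer =
# hypsometric pressure of the altitude. Gaussian sensor noise at the
# reference hardware's levels is then added, so the label timeline and the
# kinematics can never disagree. Everything is driven by one RNG seed per
# trial: identical specs give identical traces.

.fall_phases <- list(weightless_s = 0.25, impact_s = 0.15, settle_s = 0.30)

#' Describe one simulated trial
#'
#' Categories follow the fall protocols: `A` fall starting from sitting,
#' `B` fall while standing, `C` fall while standing up, and `ADL`
#' activities of daily living (no fall). Direction must be `none` for ADL
#' trials and one of the four fall directions otherwise.
#'
#' @param category `"A"`, `"B"`, `"C"` or `"ADL"`.
#' @param direction `"forward"`, `"backward"`, `"left"`, `"right"`, or
#'   `"none"` (ADL only).
#' @param seed integer RNG seed for the trial.
#' @param adl_type for ADL trials: `"sit_down"`, `"sit_down_fast"`,
#'   `"walk"`, `"lie_down"`, `"stand_up"` or `"stand_up_fast"`.
#' @param params named list of generator overrides (merged over
#'   `fallsense_config()$sim`).
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(category, direction = "none", seed = 1,
                       adl_type = "sit_down", params = list()) {
  category <- match.arg(category, c("A", "B", "C", "ADL"))
  direction <- match.arg(direction,
                         c("none", "forward", "backward", "left", "right"))
  if (category == "ADL" && direction != "none")
    stop("ADL trials must have direction 'none'")
  if (category != "ADL" && direction == "none")
    stop("fall trials need a direction")
  adl_type <- match.arg(adl_type, c("sit_down", "sit_down_fast", "walk",
                                    "lie_down", "stand_up", "stand_up_fast"))
  structure(list(category = category, direction = direction,
                 seed = as.integer(seed), adl_type = adl_type,
                 params = params),
            class = "trial_spec")
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# Build the segment script for a spec. Random magnitudes are drawn from the
# trial RNG stream (caller has already seeded it).
build_script <- function(spec, sim) {
  drop_rng <- switch(spec$category,
                     A = sim$drop_sitting_m,
                     B = sim$drop_standing_m,
                     C = sim$drop_standing_up_m,
                     NULL)
  seg <- function(kind, duration, ...) c(list(kind = kind, duration = duration),
                                         list(...))
  fall_seg <- function() {
    seg("fall", with(.fall_phases, weightless_s + impact_s + settle_s),
        direction = spec$direction,
        drop = stats::runif(1, drop_rng[1], drop_rng[2]),
        dip = stats::runif(1, sim$dip_range_g[1], sim$dip_range_g[2]),
        peak = stats::runif(1, sim$peak_range_g[1], sim$peak_range_g[2]),
        lie_angle = stats::runif(1, sim$lie_angle_range_deg[1],
                                 sim$lie_angle_range_deg[2]))
  }
  ch <- sim$chair_height_m
  script <- switch(
    spec$category,
    A = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1.5),
             seg("sit_down", 1.5, dh = -ch), seg("sit", 3.5),
             fall_seg(), seg("lying", 4)),
    B = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 2),
             fall_seg(), seg("lying", 4)),
    C = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
             seg("sit_down", 1.5, dh = -ch), seg("sit", 2.5),
             seg("stand_up", 1.4, dh = 0.4 * ch / 0.45), seg("hold", 0.5),
             fall_seg(), seg("lying", 4)),
    ADL = switch(
      spec$adl_type,
      sit_down = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
                      seg("sit_down", 1.5, dh = -ch), seg("sit", 3),
                      seg("stand_up", 1.5, dh = ch), seg("quiet", 2)),
      sit_down_fast = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
                           seg("sit_down", 0.8, dh = -ch, fast = TRUE),
                           seg("sit", 3), seg("stand_up", 1.5, dh = ch),
                           seg("quiet", 2)),
      walk = list(seg("quiet", 1.5), seg("walk", 8), seg("quiet", 2)),
      lie_down = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
                      seg("lie_down", 3, dh = -0.5), seg("lying", 4)),
      stand_up = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
                      seg("sit_down", 1.5, dh = -ch), seg("sit", 2.5),
                      seg("stand_up", 1.5, dh = ch), seg("quiet", 2)),
      stand_up_fast = list(seg("quiet", 1.5), seg("walk", 5), seg("quiet", 1),
                           seg("sit_down", 1.5, dh = -ch), seg("sit", 2.5),
                           seg("stand_up", 0.8, dh = ch, fast = TRUE),
                           seg("quiet", 2))
    )
  )
  script
}

.segment_label <- c(quiet = "STANDING", walk = "WALKING",
                    sit_down = "SITTING_DOWN", sit = "SITTING",
                    stand_up = "STANDING_UP", hold = "STANDING_UP",
                    fall = "FALLING", lying = "LYING", lie_down = "LYING")

# Synthesize the true (noise-free) per-sample kinematic series for a script.
synth_kinematics <- function(script, sim) {
  dt <- 1 / sim$rate_hz
  roll <- pitch <- alt <- gmag <- numeric(0)
  cur <- list(roll = 0, pitch = 0, alt = 0)
  walk_phase <- 0
  events <- data.frame(t = numeric(0), label = character(0))
  fall_time <- NA_real_
  t_cursor <- 0
  for (sg in script) {
    n <- max(1L, round(sg$duration / dt))
    u <- seq_len(n) / n
    tloc <- u * sg$duration
    r <- rep(cur$roll, n); p <- rep(cur$pitch, n)
    a <- rep(cur$alt, n); m <- rep(1, n)
    if (sg$kind == "walk") {
      ph <- walk_phase + 2 * pi * sim$walk_freq_hz * tloc
      m <- 1.08 + 0.22 * sin(ph)
      a <- cur$alt + 0.02 * sin(ph)
      p <- cur$pitch + 2 * sin(ph / 2)
      walk_phase <- ph[n] %% (2 * pi)
    } else if (sg$kind %in% c("sit_down", "stand_up")) {
      a <- cur$alt + sg$dh * smoothstep(u)
      fast <- isTRUE(sg$fast)
      dip <- if (fast) 0.25 else 0.15
      bump <- if (fast) 0.45 else 0.22
      sgn <- if (sg$kind == "sit_down") 1 else -1
      m <- 1 - sgn * dip * sin(pi * pmin(1, u / 0.7)) +
        bump * exp(-((u - 0.9) / 0.07)^2)
      p <- cur$pitch + 8 * sin(pi * u)
    } else if (sg$kind == "lie_down") {
      a <- cur$alt + sg$dh * smoothstep(u)
      p <- cur$pitch + (-72 - cur$pitch) * smoothstep(u)
      m <- 1 + 0.12 * sin(2 * pi * tloc / sg$duration) -
        0.08 * sin(pi * u)
    } else if (sg$kind == "fall") {
      ph <- .fall_phases
      t_w <- ph$weightless_s; t_i <- ph$impact_s
      # magnitude: ramp into weightlessness, impact spike, settle to 1 g
      m <- rep(1, n)
      wl <- tloc < t_w
      m[wl] <- 1 - (1 - sg$dip) * smoothstep(tloc[wl] / t_w)
      im <- tloc >= t_w & tloc < t_w + t_i
      m[im] <- sg$dip + (sg$peak - sg$dip) * sin(pi * (tloc[im] - t_w) / t_i)
      # body rotates toward the lying posture over the weightless+impact
      # phases; altitude drops over the same interval
      prog <- smoothstep(tloc / (t_w + t_i))
      # target absolute angles: start near upright, end at +/- lie_angle
      if (sg$direction == "forward") {
        p <- cur$pitch + ( sg$lie_angle - cur$pitch) * prog
      } else if (sg$direction == "backward") {
        p <- cur$pitch + (-sg$lie_angle - cur$pitch) * prog
      } else if (sg$direction == "right") {
        r <- cur$roll + ( sg$lie_angle - cur$roll) * prog
      } else {
        r <- cur$roll + (-sg$lie_angle - cur$roll) * prog
      }
      a <- cur$alt - sg$drop * smoothstep(tloc / (t_w + t_i + 0.1))
      fall_time <- t_cursor + t_w + t_i / 2
    }
    events <- rbind(events,
                    data.frame(t = t_cursor, label = .segment_label[[sg$kind]]))
    roll <- c(roll, r); pitch <- c(pitch, p)
    alt <- c(alt, a); gmag <- c(gmag, m)
    cur <- list(roll = r[n], pitch = p[n], alt = a[n])
    t_cursor <- t_cursor + n * dt
  }
  t <- seq_along(gmag) * dt
  list(t = t, roll = roll, pitch = pitch, alt = alt, gmag = gmag,
       events = events, fall_time = fall_time)
}

# Vectorized quaternion trajectory from roll/pitch series (yaw 0):
# q = qx(-pitch) (x) qy(roll), per sample.
angles_to_quat <- function(roll_deg, pitch_deg) {
  h1 <- -pitch_deg * pi / 360  # half of the X-rotation angle
  h2 <- roll_deg * pi / 360
  c1 <- cos(h1); s1 <- sin(h1); c2 <- cos(h2); s2 <- sin(h2)
  cbind(w = c1 * c2, x = s1 * c2, y = c1 * s2, z = s1 * s2)
}

# Exact body angular rates (rad/s) of a quaternion trajectory:
# omega = 2 q* (x) dq/dt, vectorized over rows.
quat_body_rates <- function(q, dt) {
  n <- nrow(q)
  dq <- rbind(q[2, ] - q[1, ], (q[-1, , drop = FALSE] -
                                  q[-n, , drop = FALSE])) / dt
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  dw <- dq[, 1]; dx <- dq[, 2]; dy <- dq[, 3]; dz <- dq[, 4]
  # vector part of 2 * conj(q) * dq
  wx <- 2 * (w * dx - x * dw - y * dz + z * dy)
  wy <- 2 * (w * dy + x * dz - y * dw - z * dx)
  wz <- 2 * (w * dz - x * dy + y * dx - z * dw)
  cbind(wx, wy, wz)
}

#' Simulate one trial
#'
#' Generates the 100 Hz sensor log and the ground-truth timeline for a
#' [trial_spec()]. Fully deterministic in the spec (including its seed).
#'
#' @param spec a `trial_spec`.
#' @param config a [fallsense_config()]; `config$sim` holds noise levels
#'   and kinematic defaults, overridable per trial via `spec$params`.
#' @return list with `spec`, `log` (a [sensor_log()]) and `truth` (list
#'   with `events` data frame of `(t, label)` segment starts, `fall_time`,
#'   `fall_direction`, `prefall_state`).
#' @export
simulate_trial <- function(spec, config = fallsense_config()) {
  stopifnot(inherits(spec, "trial_spec"))
  sim <- utils::modifyList(config$sim, spec$params)
  set.seed(spec$seed)
  script <- build_script(spec, sim)
  kin <- synth_kinematics(script, sim)
  n <- length(kin$t)
  dt <- 1 / sim$rate_hz

  q <- angles_to_quat(kin$roll, kin$pitch)
  v <- cbind(2 * (q[, 2] * q[, 4] - q[, 1] * q[, 3]),
             2 * (q[, 3] * q[, 4] + q[, 1] * q[, 2]),
             1 - 2 * (q[, 2]^2 + q[, 3]^2))
  acc <- v * kin$gmag
  gyr <- quat_body_rates(q, dt) * 180 / pi

  acc <- acc + matrix(stats::rnorm(3 * n, 0, sim$acc_sigma_g), n, 3)
  acc <- pmin(pmax(acc, -.sensor_spec$acc_range_g), .sensor_spec$acc_range_g)
  gyr <- gyr + matrix(stats::rnorm(3 * n, 0, sim$gyro_sigma_dps), n, 3)
  p <- altitude_to_pressure(kin$alt, sim$p_ref_pa) +
    stats::rnorm(n, 0, sim$pressure_sigma_pa)

  log <- sensor_log(data.frame(
    t = round(kin$t, 6),
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3],
    p = p
  ), rate_hz = sim$rate_hz,
  meta = list(category = spec$category, direction = spec$direction,
              seed = spec$seed,
              adl_type = if (spec$category == "ADL") spec$adl_type else "none"))

  prefall <- switch(spec$category, A = "SITTING", B = "STANDING",
                    C = "STANDING_UP", NA_character_)
  truth <- list(
    events = kin$events,
    fall_time = kin$fall_time,
    fall_direction = if (spec$category == "ADL") NA_character_ else
      toupper(spec$direction),
    prefall_state = prefall
  )
  list(spec = spec, log = log, truth = truth)
}

.adl_types_for <- list(A = c("sit_down", "sit_down_fast"),
                       B = c("walk", "lie_down"),
                       C = c("stand_up", "stand_up_fast"))

#' Simulate a balanced fall/ADL experiment
#'
#' Builds the full trial grid: `n_per_cell` fall trials for every
#' (category, direction) cell of A/B/C x forward/backward/left/right, plus
#' an equal number of matched ADL negatives per category (sit-down
#' variants for A, walking/deliberate-lying for B, stand-up variants for
#' C). Per-trial seeds are drawn once from the master seed, so the whole
#' collection is reproducible.
#'
#' @param n_per_cell trials per (category, direction) cell (>= 1).
#' @param seed master seed.
#' @param config a [fallsense_config()].
#' @return list with `trials` (list of [simulate_trial()] results) and
#'   `manifest` (data frame `id, category, direction, adl_type, seed,
#'   fall_time`).
#' @export
simulate_experiment <- function(n_per_cell, seed = 1,
                                config = fallsense_config()) {
  stopifnot(n_per_cell >= 1)
  dirs <- c("forward", "backward", "left", "right")
  cells <- expand.grid(rep = seq_len(n_per_cell), direction = dirs,
                       category = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  adl <- do.call(rbind, lapply(c("A", "B", "C"), function(cat) {
    types <- rep(.adl_types_for[[cat]], length.out = n_per_cell * 4)
    data.frame(rep = seq_along(types), direction = "none", category = "ADL",
               match_category = cat, adl_type = types,
               stringsAsFactors = FALSE)
  }))
  cells$match_category <- cells$category
  cells$adl_type <- "sit_down"
  grid <- rbind(cells, adl)
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1, nrow(grid))
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- trial_spec(grid$category[i], grid$direction[i], grid$seed[i],
                     grid$adl_type[i])
    tr <- simulate_trial(sp, config)
    tr$match_category <- grid$match_category[i]
    tr
  })
  manifest <- data.frame(
    id = seq_len(nrow(grid)),
    category = grid$category,
    match_category = grid$match_category,
    direction = grid$direction,
    adl_type = ifelse(grid$category == "ADL", grid$adl_type, "none"),
    seed = grid$seed,
    fall_time = vapply(trials, function(tr)
      ifelse(is.na(tr$truth$fall_time), NA_real_, tr$truth$fall_time),
      numeric(1))
  )
  list(trials = trials, manifest = manifest)
}

#' Write a simulated trial to disk
#'
#' Emits the sensor log as CSV and the ground truth as a JSON sidecar
#' (`<stem>.truth.json`).
#'
#' @param trial result of [simulate_trial()].
#' @param stem path stem (without extension).
#' @return paths written, invisibly.
#' @export
write_trial <- function(trial, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".truth.json")
  write_sensor_log(trial$log, csv)
  jsonlite::write_json(trial$truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(csv, js))
}
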
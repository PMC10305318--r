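cfg <- fallsense_config()

test_that("the fall rule is a strict conjunction of both thresholds", {
  lsb <- cfg$detector$accel_sensitivity_lsb_g
  expect_true(fall_rule_fires(700 / lsb, 4, cfg))
  expect_false(fall_rule_fires(700 / lsb, 2, cfg))   # pressure too small
  expect_false(fall_rule_fires(500 / lsb, 4, cfg))   # G change too small
  expect_false(fall_rule_fires(600 / lsb, 3, cfg))   # boundary: strict
  expect_false(fall_rule_fires(600 / lsb, 4, cfg))
  expect_false(fall_rule_fires(700 / lsb, 3, cfg))
})

test_that("detector fires on frames exceeding both windows, with refractory", {
  t <- seq(0.1, 12, by = 0.1)
  dg <- ifelse(t >= 5 & t <= 6, 1.5, 0.05)   # ~770 LSB for 1 s
  dp <- ifelse(t >= 5 & t <= 7, 6, 0.2)
  f <- make_frames(t, g_value = 1, dg_window = dg, dp_window = dp)
  ev <- detect_falls(f, cfg)
  expect_length(ev, 1)                        # refractory collapses the burst
  expect_gt(ev[[1]]$dg_lsb, 600)
  expect_gt(ev[[1]]$dp_pa, 3)
  # zeroing either stream suppresses every detection (conjunction property)
  expect_length(detect_falls(make_frames(t, dg_window = dg, dp_window = 0), cfg), 0)
  expect_length(detect_falls(make_frames(t, dg_window = 0, dp_window = dp), cfg), 0)
})

test_that("raising dg or dp never un-detects an event", {
  t <- seq(0.1, 8, by = 0.1)
  dg0 <- ifelse(t >= 4 & t <= 5, 1.3, 0.05)
  dp0 <- ifelse(t >= 4 & t <= 5, 4, 0.2)
  base <- detect_falls(make_frames(t, dg_window = dg0, dp_window = dp0), cfg)
  expect_length(base, 1)
  for (k in c(1.5, 3, 10)) {
    expect_length(detect_falls(make_frames(t, dg_window = dg0 * k,
                                           dp_window = dp0), cfg), 1)
    expect_length(detect_falls(make_frames(t, dg_window = dg0,
                                           dp_window = dp0 * k), cfg), 1)
  }
})

test_that("direction follows the lean-sign rule on the canonical postures", {
  expect_equal(classify_direction(0, 45), "FORWARD")
  expect_equal(classify_direction(0, -45), "BACKWARD")
  expect_equal(classify_direction(45, 0), "RIGHT")
  expect_equal(classify_direction(-45, 0), "LEFT")
  expect_equal(classify_direction(50, 5), "RIGHT")
  # tie between axes resolves to the pitch axis
  expect_equal(classify_direction(-30, 30), "FORWARD")
  dead <- classify_direction(5, 8)
  expect_true(is.na(dead))
  expect_true(attr(dead, "indeterminate"))
})

test_that("direction partitions the plane like the brute-force quadrant oracle", {
  # independent oracle: score each cardinal direction by its signed
  # coordinate and take the best, pitch axis first on ties
  oracle <- function(roll, pitch) {
    scores <- c(FORWARD = pitch, BACKWARD = -pitch, RIGHT = roll, LEFT = -roll)
    names(scores)[which.max(scores)]
  }
  grid <- expand.grid(roll = seq(-90, 90, by = 3.7),
                      pitch = seq(-90, 90, by = 3.7))
  grid <- grid[pmax(abs(grid$roll), abs(grid$pitch)) >=
                 cfg$detector$direction_angle_min_deg, ]
  got <- mapply(classify_direction, grid$roll, grid$pitch,
                MoreArgs = list(config = cfg))
  want <- mapply(oracle, grid$roll, grid$pitch)
  expect_equal(unname(got), unname(want))
  expect_setequal(unique(got), c("FORWARD", "BACKWARD", "LEFT", "RIGHT"))
})

test_that("impact magnitude is the post-weightlessness peak", {
  t <- seq(0, 3, by = 0.01)
  g <- rep(1, length(t))
  g[t >= 1 & t < 1.2] <- 0.3                 # weightless dip
  g[t >= 1.2 & t < 1.3] <- 3.2               # impact
  g[t >= 1.5 & t < 1.6] <- 2.5               # bounce
  expect_equal(as.numeric(impact_magnitude(t, g)), 3.2)
  # two peaks within the window: max semantics
  g[t >= 1.5 & t < 1.6] <- 3.0
  g[t >= 1.2 & t < 1.3] <- 2.5
  expect_equal(as.numeric(impact_magnitude(t, g)), 3.0)
  # no dip: whole-window peak, flagged
  flat <- impact_magnitude(t, rep(1, length(t)))
  expect_equal(as.numeric(flat), 1)
  expect_true(attr(flat, "no_dip"))
})

test_that("pre-fall state is the last non-falling state before impact", {
  tl <- data.frame(t = seq(0.1, 13, by = 0.1))
  tl$state <- ifelse(tl$t < 10, "WALKING",
                     ifelse(tl$t < 12, "FALLING", "LYING"))
  ev <- structure(list(t_impact = 12, flags = character(0)),
                  class = "fall_event")
  expect_equal(annotate_prefall(ev, tl)$prefall_state, "WALKING")
  tl$state[tl$t < 10] <- "STANDING_UP"
  expect_equal(annotate_prefall(ev, tl)$prefall_state, "STANDING_UP")
  tl$state[tl$t < 10] <- "INITIAL"
  ann <- annotate_prefall(ev, tl)
  expect_equal(ann$prefall_state, "INITIAL")
  expect_true("prefall_uninitialized" %in% ann$flags)
})

test_that("events serialize to JSON with all record fields", {
  ev <- structure(list(t_impact = 8.8, direction = "FORWARD",
                       impact_peak_g = 2.4, dg_lsb = 1078, dp_pa = 3.3,
                       prefall_state = "STANDING", flags = character(0)),
                  class = "fall_event")
  js <- jsonlite::fromJSON(fall_events_json(list(ev)))
  expect_equal(js$direction, "FORWARD")
  expect_equal(js$dg_lsb, 1078)
})
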
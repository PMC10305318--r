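test_that("the state alphabet has exactly eight behaviors", {
  expect_length(behavior_states(), 8)
  tab <- default_transition_table()
  expect_true(all(tab$state %in% behavior_states()))
  # falling must be reachable from every posture the fall protocols start in
  can_fall <- tab$state[tab$input == "FALLING"]
  expect_true(all(c("STANDING", "WALKING", "SITTING", "STANDING_UP",
                    "SITTING_DOWN") %in% can_fall))
})

test_that("table validation rejects duplicates, unknowns and self-inputs", {
  tab <- default_transition_table()
  expect_error(validate_transition_table(rbind(tab, tab[1, ])),
               "non-deterministic")
  bad <- tab; bad$state[1] <- "JUMPING"
  expect_error(validate_transition_table(bad), "unknown state")
  self <- tab; self$input[1] <- self$state[1]
  expect_error(validate_transition_table(self), "self-input")
})

test_that("illegal jumps are rejected: standing cannot become sitting", {
  step <- fsm_step("STANDING", "SITTING")
  expect_equal(step$state, "STANDING")
  expect_true(is.na(step$action))
  # the legal chain passes through the sit-down transition
  s1 <- fsm_step("STANDING", "SITTING_DOWN")
  expect_equal(s1$state, "SITTING_DOWN")
  expect_equal(s1$action, "sit_down")
  s2 <- fsm_step(s1$state, "SITTING")
  expect_equal(s2$state, "SITTING")
})

test_that("self-input is a no-op for every state", {
  for (s in behavior_states()) {
    step <- fsm_step(s, s)
    expect_equal(step$state, s)
    expect_true(is.na(step$action))
  }
})

test_that("fuzzing: no transition ever leaves the table", {
  tab <- default_transition_table()
  key <- paste(tab$state, tab$input)
  set.seed(99)
  state <- "STANDING"
  for (i in 1:10000) {
    input <- sample(behavior_states(), 1)
    step <- fsm_step(state, input, tab)
    expect_true(step$state %in% behavior_states())
    if (!identical(step$state, state)) {
      hit <- match(paste(state, input), key)
      expect_false(is.na(hit))
      expect_equal(step$state, tab$next_state[hit])
    }
    state <- step$state
  }
})

test_that("removing table rows only shrinks the reachable state set", {
  tab <- default_transition_table()
  reachable <- function(table, inputs) {
    state <- "STANDING"
    seen <- state
    for (input in inputs) {
      state <- fsm_step(state, input, table)$state
      seen <- union(seen, state)
    }
    seen
  }
  set.seed(5)
  for (trial in 1:20) {
    inputs <- sample(behavior_states(), 300, replace = TRUE)
    full <- reachable(tab, inputs)
    cut <- tab[-sample(nrow(tab), 5), ]
    expect_true(all(reachable(cut, inputs) %in% full))
  }
})

test_that("a quiescent trace never initializes and warns", {
  frames <- compute_features(make_quiet_log(8))
  expect_warning(tl <- run_fsm(frames), "INITIAL")
  expect_true(all(tl$state == "INITIAL"))
  expect_false(attr(tl, "initialized"))
})

test_that("frame labels: quiescent upright is standing-compatible", {
  f <- make_frames(t = seq(0.1, 2, by = 0.1), g_value = 1, pitch = 2)
  expect_equal(classify_input(f[nrow(f), ], history = f[-nrow(f), ])$label,
               "STANDING")
  # chair-band altitude drop labels a sit-down
  f2 <- make_frames(t = seq(0.1, 2, by = 0.1), dalt_window = -0.45,
                    dp_window = 5.4)
  expect_equal(classify_input(f2[nrow(f2), ], history = f2[-nrow(f2), ])$label,
               "SITTING_DOWN")
  # both fall thresholds exceeded wins over everything else
  f3 <- make_frames(t = seq(0.1, 2, by = 0.1), dalt_window = -0.45,
                    dp_window = 5.4, dg_window = 2)
  expect_equal(classify_input(f3[nrow(f3), ], history = f3[-nrow(f3), ])$label,
               "FALLING")
})

test_that("walking then a forward fall shows up in the state timeline", {
  tr <- simulate_trial(trial_spec("B", "forward", seed = 7))
  out <- run_pipeline(tr$log)
  states <- rle(out$timeline$state)$values
  expect_true("WALKING" %in% states)
  expect_true("FALLING" %in% states)
  expect_lt(which(states == "WALKING")[1], which(states == "FALLING")[1])
  expect_equal(states[length(states)], "LYING")
})

test_that("a sit-stand cycle emits the transition actions in order", {
  tr <- simulate_trial(trial_spec("ADL", "none", seed = 2,
                                  adl_type = "sit_down"))
  out <- run_pipeline(tr$log)
  acts <- out$timeline$action[!is.na(out$timeline$action)]
  expect_true(all(c("sit_down", "sat_down", "stand_up") %in% acts))
  expect_lt(which(acts == "sit_down")[1], which(acts == "stand_up")[1])
  states <- rle(out$timeline$state)$values
  expect_true(all(c("SITTING_DOWN", "SITTING", "STANDING_UP") %in% states))
})

test_that("identical frame sequences give identical timelines", {
  tr <- simulate_trial(trial_spec("A", "left", seed = 13))
  frames <- compute_features(tr$log)
  t1 <- run_fsm(frames)
  t2 <- run_fsm(frames)
  expect_identical(t1, t2)
})
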
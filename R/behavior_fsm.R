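# Mealy finite-state machine for behavior tracking.
#
# Eight states; transitions carry the output actions. Illegal
# (state, input) pairs are silently rejected: the state does not change and
# no action is emitted. This gating is the mechanism that suppresses
# physically impossible jumps (e.g. standing directly to sitting without a
# sit-down phase) and thereby reduces misjudgment.

#' The eight behavior states
#'
#' @return character vector of the state alphabet.
#' @export
behavior_states <- function() {
  c("INITIAL", "STANDING", "SITTING", "LYING", "WALKING",
    "SITTING_DOWN", "STANDING_UP", "FALLING")
}

#' Default behavior transition table
#'
#' One row per legal (state, input) pair with the successor state and the
#' Mealy output action. Falling is reachable from standing, walking,
#' sitting, standing up, and sitting down (every posture from which the
#' fall protocols start); it is not an input accepted while already lying.
#' Self-inputs are deliberately absent: repeating the current state is a
#' no-op. The table is plain data and can be edited or loaded from file
#' with [read_transition_table()].
#'
#' @return data frame with columns `state, input, next, action`.
#' @export
default_transition_table <- function() {
  e <- function(state, input, nxt, action)
    data.frame(state = state, input = input, next_state = nxt, action = action)
  tab <- rbind(
    e("INITIAL",      "WALKING",      "WALKING",      "initialized"),
    e("STANDING",     "WALKING",      "WALKING",      "walk_start"),
    e("STANDING",     "SITTING_DOWN", "SITTING_DOWN", "sit_down"),
    e("STANDING",     "LYING",        "LYING",        "lie_down"),
    e("STANDING",     "FALLING",      "FALLING",      "fall_detected"),
    e("WALKING",      "STANDING",     "STANDING",     "walk_stop"),
    e("WALKING",      "SITTING_DOWN", "SITTING_DOWN", "sit_down"),
    e("WALKING",      "FALLING",      "FALLING",      "fall_detected"),
    e("SITTING_DOWN", "SITTING",      "SITTING",      "sat_down"),
    e("SITTING_DOWN", "LYING",        "LYING",        "lie_down"),
    e("SITTING_DOWN", "FALLING",      "FALLING",      "fall_detected"),
    e("SITTING",      "STANDING_UP",  "STANDING_UP",  "stand_up"),
    e("SITTING",      "LYING",        "LYING",        "lie_down"),
    e("SITTING",      "FALLING",      "FALLING",      "fall_detected"),
    e("STANDING_UP",  "STANDING",     "STANDING",     "stood_up"),
    e("STANDING_UP",  "WALKING",      "WALKING",      "walk_start"),
    e("STANDING_UP",  "FALLING",      "FALLING",      "fall_detected"),
    e("LYING",        "SITTING",      "SITTING",      "sit_up"),
    e("LYING",        "STANDING_UP",  "STANDING_UP",  "get_up"),
    e("FALLING",      "LYING",        "LYING",        "landed"),
    e("FALLING",      "SITTING",      "SITTING",      "recovered"),
    e("FALLING",      "STANDING_UP",  "STANDING_UP",  "recovered"),
    e("FALLING",      "WALKING",      "WALKING",      "recovered")
  )
  validate_transition_table(tab)
  tab
}

#' Validate a transition table
#'
#' Checks that all states belong to the eight-state alphabet, that the
#' table is deterministic (at most one row per (state, input) pair), and
#' that no self-input rows are present.
#'
#' @param table data frame with columns `state, input, next_state, action`.
#' @return the table, invisibly.
#' @export
validate_transition_table <- function(table) {
  stopifnot(all(c("state", "input", "next_state", "action") %in% names(table)))
  states <- behavior_states()
  bad <- setdiff(unique(c(table$state, table$input, table$next_state)), states)
  if (length(bad)) stop("unknown state(s) in table: ", paste(bad, collapse = ", "))
  key <- paste(table$state, table$input)
  if (anyDuplicated(key))
    stop("non-deterministic table: duplicate (state, input) pair ",
         key[duplicated(key)][1])
  if (any(table$state == table$input))
    stop("self-input rows are not allowed (self-input is an implicit no-op)")
  invisible(table)
}

#' Read a transition table from CSV
#'
#' @param path CSV file with columns `state, input, next_state, action`.
#' @return validated transition table.
#' @export
read_transition_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  validate_transition_table(tab)
  tab
}

#' One Mealy step
#'
#' Looks up (state, input) in the table: on a hit, returns the successor
#' state and the output action; on a miss (including self-input) the state
#' is unchanged and no action is emitted.
#'
#' @param state current state (one of [behavior_states()]).
#' @param input input label (same alphabet).
#' @param table a transition table.
#' @return list with `state` and `action` (`NA_character_` when none).
#' @export
#' @examples
#' fsm_step("STANDING", "SITTING", default_transition_table())  # rejected
fsm_step <- function(state, input, table = default_transition_table()) {
  hit <- which(table$state == state & table$input == input)
  if (length(hit) == 0)
    return(list(state = state, action = NA_character_))
  list(state = table$next_state[hit], action = table$action[hit])
}

# Vectorized per-tick input labels from feature frames. One label per frame,
# by safety priority: FALLING > LYING > SITTING_DOWN / STANDING_UP >
# WALKING > STANDING (the quiescent-upright default).
classify_frames <- function(frames, config = fallsense_config()) {
  fc <- config$fsm
  dc <- config$detector
  n <- nrow(frames)
  tick <- if (!is.null(attr(frames, "tick_s"))) attr(frames, "tick_s") else
    config$fusion$decision_tick_s

  falling <- fall_rule_fires(frames$dg_window, frames$dp_window, config)

  lean <- pmax(abs(frames$roll), abs(frames$pitch))
  sustain_n <- max(1L, round(fc$lying_sustain_s / tick))
  lying <- rolling_all(lean > fc$lying_angle_deg, sustain_n)

  # chair-height altitude change with persistence: at least persist_n of
  # the trailing persist_n + 2 ticks in band, so a single noise flip at the
  # band edge does not break the run
  band <- fc$chair_band_m
  persist_n <- max(1L, round(fc$label_persist_s / tick))
  sit_raw <- frames$dalt_window <= -band[1] & frames$dalt_window >= -band[2]
  stand_raw <- frames$dalt_window >= band[1] & frames$dalt_window <= band[2]
  sitting_down <- rolling_sum(sit_raw, persist_n + 2L) >= persist_n
  standing_up <- rolling_sum(stand_raw, persist_n + 2L) >= persist_n

  walk_n <- max(1L, round(fc$walk_window_s / tick))
  g <- frames$g_value
  is_peak <- c(FALSE, g[-c(1, n)] > g[-c(n - 1, n)] &
                 g[-c(1, n)] >= g[-c(1, 2)], FALSE) & g > fc$walk_peak_g
  # gait cadence, not impact transients: the window's G range must stay in
  # the walking regime
  walking <- rolling_sum(is_peak, walk_n) >= fc$walk_min_peaks &
    frames$dg_window <= fc$walk_max_range_g

  labels <- rep("STANDING", n)
  labels[walking] <- "WALKING"
  labels[sitting_down] <- "SITTING_DOWN"
  labels[standing_up] <- "STANDING_UP"
  labels[lying] <- "LYING"
  labels[falling] <- "FALLING"
  labels
}

rolling_all <- function(x, k) {
  if (k <= 1) return(x)
  x[is.na(x)] <- FALSE
  cs <- cumsum(x)
  out <- logical(length(x))
  i <- seq_along(x)
  lo <- pmax(i - k + 1L, 1L)
  out <- (cs - c(0, cs)[lo]) == (i - lo + 1L) & (i - lo + 1L) == k
  out
}

rolling_sum <- function(x, k) {
  x[is.na(x)] <- FALSE
  cs <- cumsum(x)
  i <- seq_along(x)
  lo <- pmax(i - k + 1L, 1L)
  cs - c(0, cs)[lo]
}

#' Classify one feature frame into an input label
#'
#' Per-frame candidate behavior for the FSM. Criteria that require
#' persistence (lying, walking cadence, sit-down/stand-up) use the trailing
#' `history` frames when supplied and degrade to instantaneous checks when
#' not.
#'
#' @param frame one row of [compute_features()] output.
#' @param config a [fallsense_config()].
#' @param history optional preceding feature frames.
#' @return list with `label` (one of [behavior_states()]) and `frame`.
#' @export
classify_input <- function(frame, config = fallsense_config(), history = NULL) {
  frames <- if (is.null(history)) frame else rbind(history, frame)
  attr(frames, "tick_s") <- attr(frame, "tick_s")
  labels <- classify_frames(frames, config)
  list(label = labels[length(labels)], frame = frame)
}

#' Run the behavior state machine over a trace
#'
#' Starts in `INITIAL` and leaves it only once walking has been detected
#' for the initialization period (about three seconds of walking, i.e. the
#' wearer's ten calibration steps). After that, every tick's label is fed
#' through [fsm_step()]; transient sit-down/stand-up states resolve to
#' sitting/standing after the altitude has been quiescent for the dwell
#' period.
#'
#' @param frames output of [compute_features()].
#' @param config a [fallsense_config()].
#' @param table a transition table.
#' @return data frame `t, label, state, action` (class `fsm_timeline`);
#'   attribute `initialized` is FALSE (with a warning) when the trace ended
#'   while still in `INITIAL`.
#' @export
run_fsm <- function(frames, config = fallsense_config(),
                    table = default_transition_table()) {
  stopifnot(nrow(frames) > 0)
  fc <- config$fsm
  tick <- if (!is.null(attr(frames, "tick_s"))) attr(frames, "tick_s") else
    config$fusion$decision_tick_s
  labels <- classify_frames(frames, config)

  init_need <- round(fc$init_walk_s / tick)
  look_n <- round(fc$init_lookback_s / tick)
  walk_cnt <- rolling_sum(labels == "WALKING", look_n)
  dwell_need <- max(1L, round(fc$transient_dwell_s / tick))

  n <- nrow(frames)
  states <- character(n)
  actions <- rep(NA_character_, n)
  state <- "INITIAL"
  dwell <- 0L
  for (i in seq_len(n)) {
    input <- labels[i]
    if (state == "INITIAL") {
      if (walk_cnt[i] >= init_need) {
        state <- "WALKING"
        actions[i] <- "initialized"
      }
      states[i] <- state
      next
    }
    # transient states resolve once the altitude window has settled: hold
    # quiescent inputs as a no-op until the dwell period has elapsed
    if (state %in% c("SITTING_DOWN", "STANDING_UP") && input == "STANDING") {
      dwell <- dwell + 1L
      input <- if (dwell >= dwell_need) {
        if (state == "SITTING_DOWN") "SITTING" else "STANDING"
      } else state
    } else dwell <- 0L
    step <- fsm_step(state, input, table)
    if (!identical(step$state, state)) dwell <- 0L
    state <- step$state
    states[i] <- state
    actions[i] <- step$action
  }
  out <- data.frame(t = frames$t, label = labels, state = states,
                    action = actions)
  initialized <- any(states != "INITIAL")
  if (!initialized)
    warning("trace ended while still in INITIAL (no sustained walking found)")
  attr(out, "initialized") <- initialized
  class(out) <- c("fsm_timeline", "data.frame")
  out
}
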
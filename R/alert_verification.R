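# Two-stage fall-alert verification as pure event/timer logic.
#
# Stage one fires immediately when a fall is detected. A 30 s timer is
# armed; if at its deadline the wearer is still down (behavior state
# FALLING or LYING) the alert is confirmed and a second-stage escalation is
# emitted. The wearer can cancel within the 30 s window; a recovery seen at
# the deadline auto-resolves the alert as a false alarm. All functions take
# the current time as an argument (injected clock), so action logs are
# fully reproducible, and notifications go through a pluggable notifier
# function (the delivery infrastructure is out of scope).

#' Create an alert for a detected fall
#'
#' Builds a PENDING alert record with a deadline `verify_delay_s` (default
#' 30 s) after creation and emits the first-stage notification. The
#' notifier is called with the action when supplied; the action is returned
#' (queued) either way, so an unavailable notifier never loses the record.
#'
#' @param event a `fall_event` (or any list; carried as payload).
#' @param t_now current time (s).
#' @param config a [fallsense_config()].
#' @param notifier optional function of one argument (the action).
#' @param id record id; defaults to one derived from `t_now`.
#' @return list with `record` (class `alert_record`) and `actions` (list of
#'   one action).
#' @export
on_fall <- function(event, t_now, config = fallsense_config(),
                    notifier = NULL, id = NULL) {
  if (is.null(id)) id <- sprintf("fall-%.3f", t_now)
  record <- structure(list(
    id = id,
    t_created = t_now,
    status = "PENDING",
    t_deadline = t_now + config$alert$verify_delay_s,
    event = event
  ), class = "alert_record")
  action <- list(t = t_now, alert_id = id, action = "notify_fall",
                 channel = "speaker", stage = 1L)
  if (is.function(notifier)) try(notifier(action), silent = TRUE)
  list(record = record, actions = list(action))
}

#' Cancel a pending alert within its window
#'
#' Cancels a PENDING record when called before its deadline. Cancelling an
#' already-cancelled record is a no-op; cancelling at or after the deadline
#' is an error (the escalation decision has already been taken).
#'
#' @param record an `alert_record`.
#' @param t_now current time (s).
#' @return the updated record.
#' @export
cancel_alert <- function(record, t_now) {
  stopifnot(inherits(record, "alert_record"))
  if (record$status == "CANCELLED") return(record)
  if (record$status != "PENDING")
    stop("cannot cancel alert ", record$id, ": status is ", record$status)
  if (t_now >= record$t_deadline)
    stop("cancel window for alert ", record$id,
         " has closed; escalation already decided")
  record$status <- "CANCELLED"
  record
}

#' Advance the alert clock and escalate or resolve expired alerts
#'
#' For every PENDING record whose deadline has passed: if the wearer's
#' current behavior state is still FALLING or LYING the record is
#' CONFIRMED and a second-stage escalation action is emitted; otherwise the
#' wearer has recovered and the record auto-resolves as CANCELLED (false
#' alarm), with no escalation. Records before their deadline are untouched.
#'
#' @param records list of `alert_record`s.
#' @param current_state current behavior state (one of
#'   [behavior_states()]).
#' @param t_now current time (s).
#' @param notifier optional function called with each escalation action.
#' @return list with updated `records` and `actions`.
#' @export
alert_tick <- function(records, current_state, t_now, notifier = NULL) {
  actions <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (r$status != "PENDING" || t_now < r$t_deadline) next
    if (current_state %in% c("FALLING", "LYING")) {
      r$status <- "CONFIRMED"
      action <- list(t = t_now, alert_id = r$id, action = "escalate_fall",
                     channel = "speaker", stage = 2L)
      if (is.function(notifier)) try(notifier(action), silent = TRUE)
      actions[[length(actions) + 1L]] <- action
    } else {
      r$status <- "CANCELLED"
    }
    records[[i]] <- r
  }
  list(records = records, actions = actions)
}

#' In-memory notifier for tests and dry runs
#'
#' @return list with `notify` (the notifier function) and `log()` returning
#'   the recorded actions.
#' @export
recording_notifier <- function() {
  env <- new.env(parent = emptyenv())
  env$actions <- list()
  list(
    notify = function(action) env$actions[[length(env$actions) + 1L]] <- action,
    log = function() env$actions
  )
}

#' Serialize an action log as JSON lines
#'
#' @param actions list of action records.
#' @param path optional file; one JSON object per line.
#' @return character vector of JSON lines.
#' @export
actions_jsonl <- function(actions, path = NULL) {
  lines <- vapply(actions, function(a)
    as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)),
    character(1))
  if (!is.null(path)) writeLines(lines, path)
  lines
}
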
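# Threshold fall rule, direction and impact classification.
#
# A fall is declared when, within the trailing windows, the change in the
# resultant G value exceeds 600 raw accelerometer counts (600/512 ~ 1.17 g)
# AND the change in barometric pressure exceeds 3 Pa (~0.25 m of altitude),
# both strictly. The conjunction is what separates falls (large
# acceleration transient AND a real height drop) from sitting down (height
# drop, small transient) and from jolts (transient, no drop).

#' Does the conjunctive fall rule fire?
#'
#' @param dg_g change in resultant G over the trailing window, in g
#'   (vectorized).
#' @param dp_pa change in pressure over the trailing window, in Pa.
#' @param config a [fallsense_config()].
#' @return logical vector; TRUE where both thresholds are strictly
#'   exceeded.
#' @export
#' @examples
#' cfg <- fallsense_config()
#' fall_rule_fires(700 / 512, 4, cfg)   # TRUE
#' fall_rule_fires(600 / 512, 3, cfg)   # FALSE: strict inequalities
fall_rule_fires <- function(dg_g, dp_pa, config = fallsense_config()) {
  dc <- config$detector
  dg_lsb <- dg_g * dc$accel_sensitivity_lsb_g
  dg_lsb > dc$dg_threshold_lsb & dp_pa > dc$dp_threshold_pa
}

#' Classify the fall direction from the settled orientation
#'
#' Dominant-axis rule on the post-fall lean angles: if |pitch| >= |roll|
#' the fall was along the sagittal axis (FORWARD when pitch > 0, else
#' BACKWARD); otherwise along the lateral axis (RIGHT when roll > 0, else
#' LEFT). Sign conventions: leaning right makes roll positive, leaning
#' forward makes pitch positive. When both angles are inside the dead zone
#' the direction is indeterminate (`NA` with an `indeterminate` attribute).
#'
#' @param roll,pitch settled post-impact lean angles in degrees.
#' @param config a [fallsense_config()]; `direction_angle_min_deg` sets the
#'   dead zone.
#' @return one of `"FORWARD", "BACKWARD", "LEFT", "RIGHT"`, or `NA`.
#' @export
#' @examples
#' classify_direction(0, 45)    # FORWARD
#' classify_direction(50, 5)    # RIGHT
classify_direction <- function(roll, pitch, config = fallsense_config()) {
  amin <- config$detector$direction_angle_min_deg
  if (max(abs(roll), abs(pitch)) < amin) {
    out <- NA_character_
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  if (abs(pitch) >= abs(roll)) {
    if (pitch > 0) "FORWARD" else "BACKWARD"
  } else {
    if (roll > 0) "RIGHT" else "LEFT"
  }
}

#' Impact magnitude from the resultant-G series
#'
#' The impact is read as the peak resultant G after the weightless phase:
#' the maximum of the series between the weightlessness minimum (first dip
#' below the weightless threshold) and one second later. If the series
#' never dips below the threshold, the peak over the whole window is
#' returned with a `no_dip` attribute.
#'
#' @param t times of the series (s).
#' @param g resultant G values (g).
#' @param config a [fallsense_config()].
#' @return peak value in g; attribute `t_peak` gives its time.
#' @export
impact_magnitude <- function(t, g, config = fallsense_config()) {
  stopifnot(length(t) == length(g), length(g) > 0)
  thr <- config$detector$weightless_threshold_g
  below <- which(g < thr)
  if (length(below) == 0) {
    i <- which.max(g)
    out <- g[i]
    attr(out, "t_peak") <- t[i]
    attr(out, "no_dip") <- TRUE
    return(out)
  }
  # weightlessness minimum within the first contiguous sub-threshold run
  # (the post-impact bounce can dip again; that is not the weightless phase)
  run_end <- if (any(diff(below) > 1)) below[which(diff(below) > 1)[1]] else
    below[length(below)]
  i_dip <- below[1] - 1L + which.min(g[below[1]:run_end])
  win <- which(t >= t[i_dip] & t <= t[i_dip] + 1)
  i <- win[which.max(g[win])]
  out <- g[i]
  attr(out, "t_peak") <- t[i]
  out
}

#' Detect fall events over a trace
#'
#' Evaluates the conjunctive fall rule at every decision tick and emits at
#' most one event per refractory period. For each event: `t_impact` is the
#' time of the G peak inside the firing window, the direction is classified
#' from the orientation `direction_delay_s` after impact (the settled lying
#' posture), and the impact magnitude is the post-weightlessness peak.
#'
#' @param frames output of [compute_features()].
#' @param config a [fallsense_config()].
#' @param raw optional data frame `t, g` of the full-rate resultant G
#'   series (sharper impact peaks than the tick-rate series).
#' @return list of `fall_event` records (possibly empty); each has fields
#'   `t_impact, direction, impact_peak_g, dg_lsb, dp_pa, prefall_state,
#'   flags`.
#' @export
detect_falls <- function(frames, config = fallsense_config(), raw = NULL) {
  dc <- config$detector
  fires <- fall_rule_fires(frames$dg_window, frames$dp_window, config)
  events <- list()
  last_t <- -Inf
  g_t <- if (!is.null(raw)) raw$t else frames$t
  g_v <- if (!is.null(raw)) raw$g else frames$g_value
  for (i in which(fires)) {
    t_fire <- frames$t[i]
    if (t_fire - last_t < dc$refractory_s) next
    last_t <- t_fire
    win <- g_t >= t_fire - config$fusion$dg_window_s &
      g_t <= t_fire + config$detector$direction_delay_s
    peak <- impact_magnitude(g_t[win], g_v[win], config)
    t_impact <- attr(peak, "t_peak")
    # settled orientation after the fall
    j <- which.min(abs(frames$t - (t_impact + dc$direction_delay_s)))
    dir <- classify_direction(frames$roll[j], frames$pitch[j], config)
    flags <- character(0)
    if (isTRUE(attr(peak, "no_dip"))) flags <- c(flags, "no_dip")
    if (isTRUE(attr(dir, "indeterminate"))) flags <- c(flags, "direction_indeterminate")
    ev <- structure(list(
      t_impact = t_impact,
      t_detected = t_fire,
      direction = as.character(dir),
      impact_peak_g = as.numeric(peak),
      dg_lsb = frames$dg_window[i] * dc$accel_sensitivity_lsb_g,
      dp_pa = frames$dp_window[i],
      prefall_state = NA_character_,
      flags = flags
    ), class = "fall_event")
    events[[length(events) + 1L]] <- ev
  }
  events
}

#' Decide whether the trailing window contains a fall
#'
#' Single-shot form of [detect_falls()] over a trailing set of frames:
#' returns the first event or `NULL`.
#'
#' @inheritParams detect_falls
#' @return a `fall_event` or `NULL`.
#' @export
detect_fall <- function(frames, config = fallsense_config(), raw = NULL) {
  ev <- detect_falls(frames, config, raw)
  if (length(ev)) ev[[1]] else NULL
}

#' Attach the pre-fall behavior state to an event
#'
#' `prefall_state` is the last non-FALLING state of the behavior timeline
#' strictly before the impact; knowing whether the wearer was standing,
#' sitting, walking or mid-transition before the fall is part of the
#' clinical record. If no such state exists (trace still in INITIAL) the
#' event is flagged.
#'
#' @param event a `fall_event`.
#' @param timeline output of [run_fsm()].
#' @return the event with `prefall_state` filled in.
#' @export
annotate_prefall <- function(event, timeline) {
  prior <- timeline[timeline$t < event$t_impact &
                      timeline$state != "FALLING", , drop = FALSE]
  if (nrow(prior) == 0 || all(prior$state == "INITIAL")) {
    event$prefall_state <- "INITIAL"
    event$flags <- union(event$flags, "prefall_uninitialized")
  } else {
    st <- prior$state[prior$state != "INITIAL"]
    event$prefall_state <- st[length(st)]
  }
  event
}

#' @export
print.fall_event <- function(x, ...) {
  cat(sprintf(
    "<fall_event> t=%.2f s dir=%s peak=%.2f g dG=%.0f LSB dP=%.2f Pa prefall=%s%s\n",
    x$t_impact, x$direction, x$impact_peak_g, x$dg_lsb, x$dp_pa,
    x$prefall_state,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Serialize fall events to JSON
#'
#' @param events list of `fall_event` records.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON text (invisibly when written to file).
#' @export
fall_events_json <- function(events, path = NULL) {
  recs <- lapply(events, function(e) {
    list(t_impact = e$t_impact, direction = e$direction,
         impact_peak_g = e$impact_peak_g, dg_lsb = e$dg_lsb,
         dp_pa = e$dp_pa, prefall_state = e$prefall_state,
         flags = I(e$flags))
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
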
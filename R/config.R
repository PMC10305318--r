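#' Default pipeline configuration
#'
#' Returns the full configuration tree used by every stage of the pipeline.
#' All values are overridable, either programmatically via `...` (named
#' sublists are merged, not replaced) or from a YAML file with
#' [load_config()].
#'
#' @section Groups:
#' \describe{
#'   \item{fusion}{`beta` Madgwick gradient gain (dimensionless, default 0.1
#'     for 100 Hz operation); `dg_window_s` trailing window for the resultant-G
#'     range statistic (s); `dp_window_s` trailing window for the pressure
#'     difference, fixed at 1.5 s by the altimeter observation cadence;
#'     `decision_tick_s` feature/decision cadence (s); `kalman_q` process
#'     noise of the altitude filter (m^2); `kalman_r` measurement noise
#'     (m^2), set to the altitude-equivalent variance of the barometer noise
#'     (6 Pa at about 12 Pa/m gives sigma of roughly 0.5 m).}
#'   \item{detector}{`dg_threshold_lsb` resultant-G change threshold in raw
#'     accelerometer counts (600); `dp_threshold_pa` pressure-change
#'     threshold (3 Pa); `accel_sensitivity_lsb_g` counts per g (512);
#'     `direction_angle_min_deg` dead zone below which fall direction is
#'     indeterminate; `direction_delay_s` how long after impact the settled
#'     orientation is sampled; `weightless_threshold_g` sub-1-g level that
#'     marks the free-fall dip; `refractory_s` minimum spacing between
#'     reported events.}
#'   \item{fsm}{Behavior-classifier parameters: `lying_angle_deg` +
#'     `lying_sustain_s` for the lying posture; `chair_band_m` altitude-change
#'     band (m, within the 1.5 s window) for sit-down/stand-up; walking
#'     detection (`walk_peak_g`, `walk_min_peaks`, `walk_window_s`);
#'     `init_walk_s` walking time required to leave the initial state;
#'     `transient_dwell_s` quiescence needed for sit-down/stand-up states to
#'     resolve to sitting/standing; `label_persist_s` persistence required
#'     before a transient label is emitted.}
#'   \item{alert}{`verify_delay_s` the two-stage verification timer (30 s).}
#'   \item{sim}{Synthetic-trace generator defaults; see [simulate_trial()].}
#' }
#'
#' @param ... named overrides, e.g. `detector = list(dg_threshold_lsb = 700)`.
#' @return A nested named list with class `fallsense_config`.
#' @export
#' @examples
#' cfg <- fallsense_config(fusion = list(beta = 0.2))
#' cfg$fusion$beta
fallsense_config <- function(...) {
  cfg <- list(
    fusion = list(
      beta            = 0.1,
      dg_window_s     = 1.0,
      dp_window_s     = 1.5,
      decision_tick_s = 0.1,
      kalman_q        = 1e-4,
      kalman_r        = 0.25
    ),
    detector = list(
      dg_threshold_lsb        = 600,
      dp_threshold_pa         = 3,
      accel_sensitivity_lsb_g = 512,
      direction_angle_min_deg = 20,
      direction_delay_s       = 0.5,
      weightless_threshold_g  = 0.6,
      refractory_s            = 3
    ),
    fsm = list(
      lying_angle_deg   = 60,
      lying_sustain_s   = 1.0,
      chair_band_m      = c(0.2, 0.7),
      walk_peak_g       = 1.15,
      walk_min_peaks    = 3,
      walk_window_s     = 2,
      walk_max_range_g  = 0.9,
      init_walk_s       = 3.0,
      init_lookback_s   = 4.0,
      transient_dwell_s = 1.0,
      label_persist_s   = 0.3
    ),
    alert = list(
      verify_delay_s = 30
    ),
    sim = list(
      rate_hz           = 100,
      p_ref_pa          = 101325,
      acc_sigma_g       = 0.01,
      gyro_sigma_dps    = 0.5,
      pressure_sigma_pa = 6,
      chair_height_m    = 0.45,
      walk_freq_hz      = 2,
      dip_range_g       = c(0.2, 0.5),
      peak_range_g      = c(2.4, 3.6),
      lie_angle_range_deg = c(60, 80),
      drop_standing_m   = c(1.1, 1.3),
      drop_sitting_m    = c(0.6, 0.8),
      drop_standing_up_m = c(0.8, 1.1)
    )
  )
  class(cfg) <- c("fallsense_config", "list")
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    for (grp in names(overrides)) {
      if (!grp %in% names(cfg)) stop("unknown config group: ", grp)
      cfg[[grp]] <- utils::modifyList(cfg[[grp]], overrides[[grp]])
    }
  }
  cfg
}

#' Load a configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys are the config groups of
#' [fallsense_config()]; missing keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `fallsense_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(fallsense_config())
  do.call(fallsense_config, raw)
}
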
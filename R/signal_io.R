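#' Construct a sensor log
#'
#' A sensor log is a data frame of time-stamped IMU + barometer samples in
#' canonical physical units: time `t` in seconds since trace start,
#' acceleration `ax, ay, az` in g, angular rate `gx, gy, gz` in deg/s,
#' optional magnetic field `mx, my, mz` in microtesla, and pressure `p` in
#' pascal. The device frame is +X wearer's right, +Y anterior (out of the
#' chest), +Z superior; at quiet upright stance the accelerometer reads
#' (0, 0, 1) g.
#'
#' @param samples data frame with columns `t, ax, ay, az, gx, gy, gz, p` and
#'   optionally `mx, my, mz`.
#' @param rate_hz nominal sampling rate (Hz).
#' @param meta named list of free-form provenance entries (scalars).
#' @param validate run [validate_sensor_log()] (default TRUE).
#' @return object of class `sensor_log` (a data frame with attributes
#'   `rate_hz` and `meta`).
#' @export
sensor_log <- function(samples, rate_hz = 100, meta = list(), validate = TRUE) {
  stopifnot(is.data.frame(samples))
  required <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "p")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sensor log is missing columns: ", paste(missing, collapse = ", "))
  mag_cols <- c("mx", "my", "mz")
  has_mag <- all(mag_cols %in% names(samples))
  if (any(mag_cols %in% names(samples)) && !has_mag)
    stop("magnetometer columns must be all present or all absent")
  cols <- c(required[1], "ax", "ay", "az", "gx", "gy", "gz",
            if (has_mag) mag_cols, "p")
  log <- as.data.frame(samples)[, cols, drop = FALSE]
  rownames(log) <- NULL
  attr(log, "rate_hz") <- rate_hz
  attr(log, "meta") <- meta
  class(log) <- c("sensor_log", "data.frame")
  if (validate) validate_sensor_log(log)
  log
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf("<sensor_log> %d samples, %.0f Hz nominal, %.2f s, %s magnetometer\n",
              nrow(x), attr(x, "rate_hz"),
              if (nrow(x)) max(x$t) - min(x$t) else 0,
              if (has_mag(x)) "with" else "no"))
  invisible(x)
}

has_mag <- function(log) all(c("mx", "my", "mz") %in% names(log))

#' Validate a sensor log
#'
#' Checks the structural invariants of a trace: timestamps non-negative and
#' strictly increasing, pressure within the barometer operating range
#' (300-1100 hPa), acceleration within the accelerometer operating range
#' (+/- 4 g), and median inter-sample interval within 10% of the nominal
#' rate.
#'
#' @param log a `sensor_log`.
#' @return the log, invisibly; otherwise an error whose message names the
#'   first offending row.
#' @export
validate_sensor_log <- function(log) {
  if (!nrow(log)) return(invisible(log))
  if (any(log$t < 0))
    stop("validation error: negative timestamp at row ", which(log$t < 0)[1])
  if (nrow(log) > 1) {
    dt <- diff(log$t)
    bad <- which(dt <= 0)
    if (length(bad))
      stop("validation error: non-monotonic timestamps at row ", bad[1] + 1)
    rate <- attr(log, "rate_hz")
    if (!is.null(rate) && nrow(log) >= 10) {
      med <- stats::median(dt)
      if (abs(med - 1 / rate) > 0.1 / rate)
        stop("validation error: median sample interval ", signif(med, 4),
             " s inconsistent with nominal rate ", rate, " Hz")
    }
  }
  pr <- .sensor_spec$pressure_range_pa
  bad_p <- which(log$p < pr[1] | log$p > pr[2])
  if (length(bad_p))
    stop("validation error: pressure out of operating range at row ", bad_p[1])
  amax <- .sensor_spec$acc_range_g
  acc <- abs(as.matrix(log[, c("ax", "ay", "az")]))
  bad_a <- which(apply(acc, 1, max) > amax + 1e-9)
  if (length(bad_a))
    stop("validation error: acceleration beyond +/-", amax,
         " g at row ", bad_a[1])
  invisible(log)
}

#' Read a sensor log from CSV
#'
#' The dialect is comma-separated UTF-8 with a mandatory header and '.'
#' decimal separator. Provenance metadata is carried in `#`-prefixed
#' `key: value` lines before the header. Files may carry either canonical
#' physical units or raw sensor counts; the latter is declared with a
#' `# raw_lsb: true` metadata line and converted on read using the reference
#' sensitivities (512 LSB/g, 32.8 LSB/deg/s, 3.3 LSB/uT, 6 LSB/Pa).
#'
#' @param path file path.
#' @param rate_hz nominal rate; taken from a `rate_hz` metadata line when
#'   present.
#' @param validate run validation after reading (default TRUE).
#' @return a [sensor_log()].
#' @export
read_sensor_log <- function(path, rate_hz = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1 else length(lines)
  meta <- list()
  if (n_meta > 0) {
    for (ln in lines[seq_len(n_meta)]) {
      kv <- sub("^#\\s*", "", ln)
      if (!grepl(":", kv)) next
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
  }
  body <- lines[-seq_len(n_meta)]
  if (!length(body)) stop("format error: no header row in ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  required <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "p")
  if (!all(required %in% header))
    stop("format error: header must contain columns ",
         paste(required, collapse = ", "), "; got: ", body[1])
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "numeric")
  raw_lsb <- isTRUE(meta$raw_lsb) || identical(meta$raw_lsb, "true")
  if (raw_lsb) {
    s <- .sensor_spec
    for (cc in c("ax", "ay", "az")) df[[cc]] <- df[[cc]] / s$lsb_per_g
    for (cc in c("gx", "gy", "gz")) df[[cc]] <- df[[cc]] / s$lsb_per_dps
    for (cc in intersect(c("mx", "my", "mz"), names(df)))
      df[[cc]] <- df[[cc]] / s$lsb_per_ut
    df$p <- df$p / s$lsb_per_pa
    meta$raw_lsb <- NULL
  }
  if (is.null(rate_hz))
    rate_hz <- if (!is.null(meta$rate_hz)) as.numeric(meta$rate_hz) else 100
  meta$rate_hz <- NULL
  sensor_log(df, rate_hz = rate_hz, meta = meta, validate = validate)
}

#' Write a sensor log to CSV
#'
#' Inverse of [read_sensor_log()]: metadata as `#`-prefixed comment lines,
#' then the header, then one row per sample. Values are written with enough
#' digits that a read/write round trip reproduces every field to at least 6
#' significant digits; absent magnetometer columns are omitted.
#'
#' @param log a `sensor_log`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  validate_sensor_log(log)
  meta <- attr(log, "meta")
  rate <- attr(log, "rate_hz")
  hdr <- c(
    sprintf("# rate_hz: %s", format(rate)),
    if (length(meta))
      vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
             character(1))
  )
  cols <- names(log)
  rows <- if (nrow(log)) {
    cells <- vapply(cols, function(cc) sprintf("%.10g", log[[cc]]),
                    character(nrow(log)))
    if (nrow(log) == 1L) paste(cells, collapse = ",")
    else apply(cells, 1, paste, collapse = ",")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = ","), rows), con, useBytes = TRUE)
  invisible(path)
}
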
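#' Build an hourly radon-concentration series
#'
#' Active monitors report the radon concentration in kBq m^-3 on an hourly
#' grid. Timestamps must be strictly increasing (nominally 1 h apart) and
#' concentrations nonnegative.
#'
#' @param code participant code of the reporting device (an active monitor),
#'   or a label such as `"truth"` for reference series.
#' @param timestamps POSIXct vector (or parseable strings), strictly
#'   increasing.
#' @param concentration_kBqm3 numeric vector, same length, all >= 0.
#' @return A data.frame of class `c("monitor_series", "data.frame")` with
#'   columns `code`, `timestamp`, `concentration_kBqm3`.
#' @export
monitor_series <- function(code, timestamps, concentration_kBqm3) {
  timestamps <- as_campaign_time(timestamps)
  if (length(timestamps) != length(concentration_kBqm3)) {
    stop("'timestamps' and 'concentration_kBqm3' lengths differ", call. = FALSE)
  }
  if (length(timestamps) < 1L || anyNA(timestamps)) {
    stop("'timestamps' must be non-empty and valid", call. = FALSE)
  }
  if (any(diff(as.numeric(timestamps)) <= 0)) {
    stop("'timestamps' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(concentration_kBqm3) | concentration_kBqm3 < 0)) {
    stop("'concentration_kBqm3' must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(code = as.character(code), timestamp = timestamps,
                    concentration_kBqm3 = as.numeric(concentration_kBqm3),
                    stringsAsFactors = FALSE)
  class(out) <- c("monitor_series", "data.frame")
  out
}

#' Read / write hourly monitor series as CSV
#'
#' Column layout: `code,timestamp_iso8601,concentration_kBqm3`, one header
#' line, `.` decimal separator, UTF-8. Timestamps are ISO 8601
#' (`YYYY-MM-DDTHH:MM:SS`) in naive campaign-local time.
#'
#' @param path CSV path.
#' @return `read_monitor_series`: a `monitor_series` data.frame (possibly with
#'   several codes stacked); `write_monitor_series`: `path`, invisibly.
#' @export
read_monitor_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("code", "timestamp_iso8601", "concentration_kBqm3")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("monitor series file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parts <- split(x, x$code)
  out <- do.call(rbind, lapply(parts, function(p) {
    monitor_series(p$code[1],
                   as.POSIXct(p$timestamp_iso8601, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S"),
                   p$concentration_kBqm3)
  }))
  rownames(out) <- NULL
  class(out) <- c("monitor_series", "data.frame")
  out
}

#' @rdname read_monitor_series
#' @param x a `monitor_series` data.frame.
#' @export
write_monitor_series <- function(x, path) {
  stopifnot(all(c("code", "timestamp", "concentration_kBqm3") %in% names(x)))
  out <- data.frame(
    code = x$code,
    timestamp_iso8601 = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    concentration_kBqm3 = x$concentration_kBqm3
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integrate an hourly concentration series to an exposure
#'
#' Converts an hourly radon-concentration series (kBq m^-3) into the
#' time-integrated exposure (kBq m^-3 h) over an exposure window. The default
#' rule is the left-rectangular sum on the hourly grid: each sample represents
#' the hour that follows it, so the exposure is the plain sum of in-window
#' samples times 1 h. Window membership is half-open, `[start, end)`, so two
#' adjacent windows never double-count an hour. A trapezoidal rule is
#' available as an option (it additionally uses the first sample at or after
#' `end` as the closing ordinate).
#'
#' @param series a `monitor_series` data.frame for a single device.
#' @param window an [exposure_window()]; must be covered by the series
#'   (samples at or before `start`, and up to the last in-window hour).
#' @param rule `"left"` (default) or `"trapezoid"`.
#' @return Exposure in kBq m^-3 h (nonnegative for a nonnegative series).
#' @examples
#' w <- exposure_window("E1", "2018-11-05 12:00", "2018-11-06 01:00")
#' s <- monitor_series("L01A1", w$start + 3600 * (0:12), rep(10, 13))
#' integrate_exposure(s, w) # 130
#' @export
integrate_exposure <- function(series, window, rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(window, "exposure_window"))
  if (length(unique(series$code)) > 1L) {
    stop("'series' must contain a single device; got codes: ",
         paste(unique(series$code), collapse = ", "), call. = FALSE)
  }
  t <- as.numeric(series$timestamp)
  c_kbq <- series$concentration_kBqm3
  t0 <- as.numeric(window$start)
  t1 <- as.numeric(window$end)
  if (min(t) > t0 || max(t) < t1 - 3600) {
    stop(sprintf(
      "series does not cover window '%s': need samples from %s through %s",
      window$label, format(window$start, "%Y-%m-%d %H:%M"),
      format(window$end - 3600, "%Y-%m-%d %H:%M")), call. = FALSE)
  }
  inside <- t >= t0 & t < t1
  if (rule == "left") {
    sum(c_kbq[inside])
  } else {
    idx <- which(inside)
    nxt <- max(idx) + 1L
    tt <- c(t[idx], if (nxt <= length(t)) t[nxt] else t1) / 3600
    cc <- c(c_kbq[idx], if (nxt <= length(t)) c_kbq[nxt] else c_kbq[max(idx)])
    sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  }
}
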
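#' Define an exposure window
#'
#' An exposure window is the labelled time interval over which detectors
#' accumulate radon exposure, together with the fraction of the assigned value
#' used as the standard deviation for proficiency assessment (sigma_p) in the
#' z-score. Timestamps are naive campaign-local time; they are stored as
#' POSIXct in UTC purely as a fixed-offset container and no timezone
#' arithmetic is ever applied.
#'
#' @param label window label: `"E1"`, `"E2"`, or any custom string.
#' @param start,end POSIXct timestamps (or strings parseable as
#'   `"%Y-%m-%d %H:%M"`); `end` must be strictly after `start`.
#' @param sigma_p_fraction sigma_p as a fraction of the assigned value, in
#'   (0, 1]. Defaults to 0.20 for `"E1"` and 0.10 for `"E2"`; mandatory for
#'   custom labels.
#' @return An object of class `exposure_window`.
#' @examples
#' exposure_window("E1", "2018-11-05 12:00", "2018-11-06 01:00")
#' @export
exposure_window <- function(label, start, end, sigma_p_fraction = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  start <- as_campaign_time(start)
  end <- as_campaign_time(end)
  if (is.na(start) || is.na(end)) {
    stop("'start'/'end' must be valid timestamps", call. = FALSE)
  }
  if (end <= start) {
    stop("window '", label, "': 'end' must be strictly after 'start'",
         call. = FALSE)
  }
  if (is.null(sigma_p_fraction)) {
    sigma_p_fraction <- switch(label, E1 = 0.20, E2 = 0.10,
      stop("'sigma_p_fraction' must be given for custom window '", label, "'",
           call. = FALSE))
  }
  if (!is.numeric(sigma_p_fraction) || length(sigma_p_fraction) != 1L ||
      is.na(sigma_p_fraction) || sigma_p_fraction <= 0 || sigma_p_fraction > 1) {
    stop("'sigma_p_fraction' must be a single number in (0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, start = start, end = end,
         sigma_p_fraction = sigma_p_fraction),
    class = "exposure_window"
  )
}

as_campaign_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), tz = "UTC",
                                                origin = "1970-01-01"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d"))
  out
}

#' Duration of an exposure window in hours
#'
#' @param window an [exposure_window()].
#' @return numeric, hours.
#' @export
window_hours <- function(window) {
  stopifnot(inherits(window, "exposure_window"))
  as.numeric(difftime(window$end, window$start, units = "hours"))
}

#' The campaign's default exposure windows
#'
#' The two overlapping exposure periods of the November 2018 LNR (Laboratory
#' of Natural Radiation) field intercomparison: both start at the same moment;
#' E1 lasts 13 h and E2 lasts 70 h. sigma_p is 20% of the assigned value for
#' E1 and 10% for E2.
#'
#' @return Named list of two `exposure_window` objects, `E1` and `E2`.
#' @examples
#' vapply(default_windows(), window_hours, numeric(1)) # 13, 70
#' @export
default_windows <- function() {
  list(
    E1 = exposure_window("E1", "2018-11-05 12:00", "2018-11-06 01:00", 0.20),
    E2 = exposure_window("E2", "2018-11-05 12:00", "2018-11-08 10:00", 0.10)
  )
}

#' @export
print.exposure_window <- function(x, ...) {
  cat(sprintf("Exposure window %s: %s -> %s (%.6g h), sigma_p = %g%% of E_ref\n",
              x$label, format(x$start, "%Y-%m-%d %H:%M"),
              format(x$end, "%Y-%m-%d %H:%M"), window_hours(x),
              100 * x$sigma_p_fraction))
  invisible(x)
}
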
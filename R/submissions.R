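#' Validate a table of participant submissions
#'
#' A submission is one participant result for one exposure window: the
#' time-integrated radon exposure in kBq m^-3 h and its standard uncertainty
#' at coverage factor k = 1. Exposure and uncertainty must be nonnegative and
#' finite, codes must parse, window labels must be known, and the
#' (code, window) pair must be unique within a campaign.
#'
#' @param x data.frame with columns `code`, `window`, `exposure_kBqm3h`,
#'   `u_k1_kBqm3h`.
#' @param windows named list of [exposure_window()] objects defining the legal
#'   window labels (default [default_windows()]).
#' @return The validated data.frame (invisibly unchanged apart from canonical
#'   code serialisation), with class `c("radon_submissions", "data.frame")`.
#' @export
as_submissions <- function(x, windows = default_windows()) {
  required <- c("code", "window", "exposure_kBqm3h", "u_k1_kBqm3h")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("submissions are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$code <- parse_code(as.character(x$code))$code
  labels <- vapply(windows, `[[`, character(1), "label")
  bad_win <- !(x$window %in% labels)
  if (any(bad_win)) {
    stop("unknown window label(s) at row(s) ",
         paste(which(bad_win), collapse = ", "), ": ",
         paste(unique(x$window[bad_win]), collapse = ", "), call. = FALSE)
  }
  for (col in c("exposure_kBqm3h", "u_k1_kBqm3h")) {
    v <- x[[col]]
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop("'", col, "' must be finite and >= 0; offending row(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(x$code, x$window)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (code, window) pair(s) at row(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  }
  class(x) <- c("radon_submissions", "data.frame")
  x
}

#' Read participant submissions from CSV
#'
#' Expects one header line and the columns
#' `code,window,exposure_kBqm3h,u_k1_kBqm3h` with `.` as the decimal
#' separator (UTF-8). Units are fixed campaign-wide; a file declaring other
#' units (different column names) is rejected rather than converted.
#'
#' @param path path to a CSV file.
#' @inheritParams as_submissions
#' @return Validated submissions data.frame, see [as_submissions()].
#' @export
read_submissions <- function(path, windows = default_windows()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_submissions(x, windows = windows)
}

#' Write participant submissions to CSV
#'
#' @param x submissions data.frame (validated with [as_submissions()] first).
#' @param path output path.
#' @inheritParams as_submissions
#' @return `path`, invisibly.
#' @export
write_submissions <- function(x, path, windows = default_windows()) {
  x <- as_submissions(x, windows = windows)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
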
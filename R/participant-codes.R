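#' Parse participant codes
#'
#' Campaign results are anonymised with codes of the form `LxxTn`: `xx` is the
#' two-digit (zero-padded) lab number from 01 to 99, `T` is the device class
#' (`A` for an active monitor, `P` for a group of passive detectors) and `n`
#' is the positive group index distinguishing multiple participations of the
#' same lab. `"L07P1"` is lab 7's first passive-detector group.
#'
#' Parsing is strict: any malformed code (wrong leading letter, unknown device
#' letter, non-numeric lab number or group index, lab number 0) is an error
#' naming the offending code, never a silent default.
#'
#' @param code character vector of codes such as `"L07P1"`.
#' @return A data.frame with one row per code and columns `code` (the
#'   canonical re-serialised form), `lab_number` (integer), `device_kind`
#'   (`"active"` or `"passive"`) and `group_index` (integer).
#' @seealso [format_code()] for the inverse operation.
#' @examples
#' parse_code(c("L07P1", "L12A1"))
#' @export
parse_code <- function(code) {
  if (!is.character(code) || length(code) == 0) {
    stop("'code' must be a non-empty character vector", call. = FALSE)
  }
  m <- regmatches(code, regexec("^L([0-9]{2})([AP])([1-9][0-9]*)$", code))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed participant code(s): ",
         paste(sQuote(code[bad]), collapse = ", "),
         " (expected 'LxxTn', e.g. 'L07P1')", call. = FALSE)
  }
  lab <- as.integer(vapply(m, `[`, character(1), 2L))
  if (any(lab < 1L)) {
    stop("lab number must be 01-99 in code(s): ",
         paste(sQuote(code[lab < 1L]), collapse = ", "), call. = FALSE)
  }
  kind <- ifelse(vapply(m, `[`, character(1), 3L) == "A", "active", "passive")
  grp <- as.integer(vapply(m, `[`, character(1), 4L))
  data.frame(
    code = format_code(lab, kind, grp),
    lab_number = lab,
    device_kind = kind,
    group_index = grp,
    stringsAsFactors = FALSE
  )
}

#' Serialise participant codes
#'
#' Inverse of [parse_code()]: builds the canonical `LxxTn` text form.
#'
#' @param lab_number integer vector, 1-99.
#' @param device_kind `"active"` or `"passive"` (vector, recycled).
#' @param group_index positive integer vector.
#' @return character vector of codes.
#' @examples
#' format_code(7, "passive", 1) # "L07P1"
#' @export
format_code <- function(lab_number, device_kind, group_index) {
  lab_number <- as.integer(lab_number)
  group_index <- as.integer(group_index)
  if (any(is.na(lab_number)) || any(lab_number < 1L) || any(lab_number > 99L)) {
    stop("'lab_number' must be an integer in 1-99", call. = FALSE)
  }
  if (any(is.na(group_index)) || any(group_index < 1L)) {
    stop("'group_index' must be a positive integer", call. = FALSE)
  }
  letter <- c(active = "A", passive = "P")[device_kind]
  if (any(is.na(letter))) {
    stop("'device_kind' must be 'active' or 'passive'", call. = FALSE)
  }
  sprintf("L%02d%s%d", lab_number, letter, group_index)
}

#' Device class of participant codes
#'
#' @param code character vector of `LxxTn` codes.
#' @return character vector, `"active"` or `"passive"`.
#' @export
device_kind <- function(code) {
  parse_code(code)$device_kind
}
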
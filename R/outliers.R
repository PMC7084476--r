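#' IQR (boxplot) outlier screen for one exposure window
#'
#' Flags results lying more than 1.5 interquartile ranges outside the
#' quartiles: with `IQR = Q3 - Q1`, the fences are `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR` and a result is an outlier when it falls strictly outside
#' them (a value exactly on a fence is not an outlier). Quartiles use linear
#' interpolation of order statistics by default (the common
#' spreadsheet/default convention, `stats::quantile` type 7); Tukey hinges
#' are available via `quartile_method = "hinges"`.
#'
#' The screen also recomputes the robust consensus without the flagged
#' results so the two assigned-value variants can be compared with
#' [sensitivity_check()].
#'
#' @param submissions submissions data.frame (see [as_submissions()]).
#' @param window an [exposure_window()]; at least 4 results required.
#' @param quartile_method `"linear"` (default) or `"hinges"`.
#' @param ... passed to [consensus_for_window()].
#' @return A list of class `outlier_report`: `window_label`, `q1`, `q3`,
#'   `iqr`, `lower_fence`, `upper_fence`, `outlier_codes`, `e_ref_all`,
#'   `u_e_ref_all`, `e_ref_without_outliers`, `u_e_ref_without_outliers`.
#' @export
iqr_outliers <- function(submissions, window,
                         quartile_method = c("linear", "hinges"), ...) {
  quartile_method <- match.arg(quartile_method)
  stopifnot(inherits(window, "exposure_window"))
  rows <- submissions[submissions$window == window$label, , drop = FALSE]
  if (nrow(rows) < 4L) {
    stop("window '", window$label,
         "' has fewer than 4 results; quartiles are not meaningful",
         call. = FALSE)
  }
  v <- rows$exposure_kBqm3h
  if (quartile_method == "linear") {
    q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    fn <- stats::fivenum(v)
    q <- fn[c(2, 4)]
  }
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  out_idx <- v < lower | v > upper
  all_fit <- consensus_for_window(rows, window, ...)
  keep <- rows[!out_idx, , drop = FALSE]
  if (nrow(keep) >= 2L) {
    wo_fit <- consensus_for_window(keep, window, ...)
    e_wo <- wo_fit$e_ref
    u_wo <- wo_fit$u_e_ref
  } else {
    e_wo <- NA_real_
    u_wo <- NA_real_
  }
  structure(list(
    window_label = window$label,
    q1 = q[1], q3 = q[2], iqr = iqr,
    lower_fence = lower, upper_fence = upper,
    outlier_codes = rows$code[out_idx],
    e_ref_all = all_fit$e_ref,
    u_e_ref_all = all_fit$u_e_ref,
    e_ref_without_outliers = e_wo,
    u_e_ref_without_outliers = u_wo
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("IQR outlier screen for %s\n", x$window_label))
  cat(sprintf("  Q1 = %.6g, Q3 = %.6g, IQR = %.6g, fences [%.6g, %.6g]\n",
              x$q1, x$q3, x$iqr, x$lower_fence, x$upper_fence))
  if (length(x$outlier_codes)) {
    cat("  outliers:", paste(x$outlier_codes, collapse = ", "), "\n")
  } else {
    cat("  no outliers\n")
  }
  cat(sprintf("  E_ref all results: %.6g; without outliers: %.6g\n",
              x$e_ref_all, x$e_ref_without_outliers))
  invisible(x)
}

#' Consensus sensitivity to outlier removal
#'
#' Operationalises "no statistical difference" between the assigned value
#' computed from all results and the one computed without IQR outliers: the
#' two variants agree when their difference is within two combined standard
#' uncertainties, `|E_all - E_wo| <= 2 sqrt(u_all^2 + u_wo^2)`.
#'
#' @param report an `outlier_report` from [iqr_outliers()].
#' @return logical: `TRUE` when the two assigned values are statistically
#'   indistinguishable (so all results may be kept for the consensus).
#' @export
sensitivity_check <- function(report) {
  stopifnot(inherits(report, "outlier_report"))
  if (is.na(report$e_ref_without_outliers)) {
    stop("outlier-free consensus unavailable (too few remaining results)",
         call. = FALSE)
  }
  diff <- abs(report$e_ref_all - report$e_ref_without_outliers)
  u <- sqrt(report$u_e_ref_all^2 + report$u_e_ref_without_outliers^2)
  diff <= 2 * u
}
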
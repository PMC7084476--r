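#' Robust consensus estimate (ISO 13528:2015 Algorithm A)
#'
#' Computes the robust average `E_ref` and robust standard deviation `s*` of a
#' set of participant results by the iterative winsorisation scheme of ISO
#' 13528:2015, Algorithm A. Extreme values are not discarded: they are
#' relocated to the edge of the acceptable band, so every result contributes
#' while none dominates.
#'
#' The iteration is:
#' \enumerate{
#'   \item initialise `E_ref` = median of the values and
#'     `s*` = 1.483 x median of the absolute deviations from that median;
#'   \item set `delta = 1.5 * s*` and winsorise each value into
#'     `[E_ref - delta, E_ref + delta]`;
#'   \item update `E_ref` = mean of the winsorised values and
#'     `s*` = 1.134 x their standard deviation;
#'   \item repeat 2-3 until both `E_ref` and `s*` change by less than `tol`
#'     in relative terms, or `max_iterations` is reached.
#' }
#'
#' If the initial median absolute deviation is zero the algorithm
#' short-circuits: winsorising with `delta = 0` would freeze every value at
#' the median anyway, so `(median, 0)` is returned immediately with
#' `degenerate = TRUE`.
#'
#' @param values numeric vector of at least 2 finite results (kBq m^-3 h in
#'   this campaign, but the estimator is unit-agnostic).
#' @param tol relative convergence tolerance on both `E_ref` and `s*`
#'   (default 1e-9; far tighter than the "no change in the third significant
#'   figure" working rule, and the iteration count is reported).
#' @param max_iterations iteration cap (default 1000).
#' @param sd_denominator `"sample"` (n - 1, default) or `"population"` (n)
#'   for the standard deviation in the update step.
#' @return A list of class `algorithm_a` with elements `e_ref`, `s_star`,
#'   `iterations`, `converged`, `degenerate`, `p` (number of results).
#' @examples
#' algorithm_a(c(1, 2, 3, 4, 100))
#' @export
algorithm_a <- function(values, tol = 1e-9, max_iterations = 1000L,
                        sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!is.numeric(values) || length(values) < 2L) {
    stop("need at least 2 values for a robust consensus", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("all values must be finite", call. = FALSE)
  }
  p <- length(values)
  e_ref <- stats::median(values)
  s_star <- 1.483 * stats::median(abs(values - e_ref))
  if (s_star == 0) {
    return(structure(list(e_ref = e_ref, s_star = 0, iterations = 0L,
                          converged = TRUE, degenerate = TRUE, p = p),
                     class = "algorithm_a"))
  }
  sd_fun <- if (sd_denominator == "sample") {
    stats::sd
  } else {
    function(x) sqrt(mean((x - mean(x))^2))
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    delta <- 1.5 * s_star
    w <- pmin(pmax(values, e_ref - delta), e_ref + delta)
    e_new <- mean(w)
    s_new <- 1.134 * sd_fun(w)
    de <- abs(e_new - e_ref) / max(abs(e_ref), .Machine$double.eps)
    ds <- abs(s_new - s_star) / max(abs(s_star), .Machine$double.eps)
    e_ref <- e_new
    s_star <- s_new
    if (de < tol && ds < tol) {
      converged <- TRUE
      break
    }
    if (s_star == 0) break # collapsed spread; nothing further can move
  }
  structure(list(e_ref = e_ref, s_star = s_star, iterations = iter,
                 converged = converged, degenerate = FALSE, p = p),
            class = "algorithm_a")
}

#' @export
print.algorithm_a <- function(x, ...) {
  cat(sprintf("Algorithm A: E_ref = %.6g, s* = %.6g (p = %d, %d iteration%s%s)\n",
              x$e_ref, x$s_star, x$p, x$iterations,
              if (x$iterations == 1L) "" else "s",
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Standard uncertainty of the assigned value
#'
#' For a consensus assigned value obtained with Algorithm A from `p` results
#' with robust standard deviation `s*`, the standard uncertainty is
#' `u(E_ref) = 1.25 * s* / sqrt(p)`.
#'
#' @param s_star robust standard deviation (>= 0).
#' @param p number of results (>= 1).
#' @return standard uncertainty, same units as `s_star`.
#' @examples
#' uncertainty_of_reference(43, 45) # 8.014...
#' @export
uncertainty_of_reference <- function(s_star, p) {
  if (!is.numeric(p) || any(p < 1)) stop("'p' must be >= 1", call. = FALSE)
  if (!is.numeric(s_star) || any(s_star < 0)) {
    stop("'s_star' must be >= 0", call. = FALSE)
  }
  1.25 * s_star / sqrt(p)
}

#' Robust consensus for one exposure window
#'
#' Runs [algorithm_a()] on all submissions of one window and assembles the
#' full set of reference parameters: the assigned value `E_ref`, the robust
#' standard deviation `s*`, the standard uncertainty
#' `u(E_ref) = 1.25 s*/sqrt(p)`, the standard deviation for proficiency
#' assessment `sigma_p` (the window's stated fraction of `E_ref`), and the
#' fitness criterion `u(E_ref) < 0.3 sigma_p` that certifies the assigned
#' value is precise enough to score against.
#'
#' @param submissions submissions data.frame (see [as_submissions()]); only
#'   rows matching `window$label` are used, and there must be at least 2.
#' @param window an [exposure_window()].
#' @param min_p minimum number of results below which a non-fatal quality
#'   warning flag is set (default 5).
#' @param ... passed to [algorithm_a()] (`tol`, `max_iterations`,
#'   `sd_denominator`).
#' @return A list of class `consensus_result`: `window_label`, `e_ref`,
#'   `s_star`, `u_e_ref`, `p`, `sigma_p`, `sigma_p_fraction`, `iterations`,
#'   `converged`, `criterion_ok`, `low_p_warning`.
#' @export
consensus_for_window <- function(submissions, window, min_p = 5L, ...) {
  stopifnot(inherits(window, "exposure_window"))
  rows <- submissions[submissions$window == window$label, , drop = FALSE]
  if (nrow(rows) < 2L) {
    stop("window '", window$label, "' has fewer than 2 submissions",
         call. = FALSE)
  }
  fit <- algorithm_a(rows$exposure_kBqm3h, ...)
  u <- uncertainty_of_reference(fit$s_star, fit$p)
  sigma_p <- window$sigma_p_fraction * fit$e_ref
  structure(list(
    window_label = window$label,
    e_ref = fit$e_ref,
    s_star = fit$s_star,
    u_e_ref = u,
    p = fit$p,
    sigma_p = sigma_p,
    sigma_p_fraction = window$sigma_p_fraction,
    iterations = fit$iterations,
    converged = fit$converged,
    criterion_ok = is.finite(sigma_p) && sigma_p > 0 && u < 0.3 * sigma_p,
    low_p_warning = fit$p < min_p
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus for %s: E_ref = %.6g kBq m-3 h, u(E_ref) = %.3g, sigma_p = %.4g, s* = %.4g, p = %d\n",
              x$window_label, x$e_ref, x$u_e_ref, x$sigma_p, x$s_star, x$p))
  cat(sprintf("  u(E_ref) < 0.3 sigma_p: %s%s\n",
              if (x$criterion_ok) "met" else "NOT met",
              if (x$low_p_warning) sprintf(" [warning: p = %d is small]", x$p) else ""))
  invisible(x)
}
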
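#' Run the full proficiency-testing pipeline
#'
#' Executes, per exposure window and in order: robust consensus
#' ([consensus_for_window()]), performance scoring ([score_submissions()]),
#' the IQR outlier screen ([iqr_outliers()]) with its sensitivity check, and
#' the per-class summary table ([summary_table()]). Deterministic for fixed
#' input.
#'
#' @param submissions submissions data.frame (see [as_submissions()]).
#' @param windows named list of [exposure_window()]s (default
#'   [default_windows()]).
#' @param min_p minimum result count before a quality warning, passed to
#'   [consensus_for_window()].
#' @param ... passed to [algorithm_a()] via the consensus stage.
#' @return list of class `radon_pt_results`: `consensus` (named list of
#'   `consensus_result`), `scores` (stacked score records), `outliers`
#'   (named list of `outlier_report` plus `$sensitivity_ok` flags), `summary`
#'   (the [summary_table()] data.frame), `windows`.
#' @export
run_pipeline <- function(submissions, windows = default_windows(),
                         min_p = 5L, ...) {
  submissions <- as_submissions(submissions, windows = windows)
  consensus <- list()
  scores <- list()
  outliers <- list()
  for (wl in names(windows)) {
    w <- windows[[wl]]
    n_w <- sum(submissions$window == w$label)
    if (n_w == 0L) {
      stop("pipeline stage 'consensus': window '", w$label,
           "' has no submissions", call. = FALSE)
    }
    consensus[[wl]] <- tryCatch(
      consensus_for_window(submissions, w, min_p = min_p, ...),
      error = function(e) stop("pipeline stage 'consensus' (window '",
                               w$label, "'): ", conditionMessage(e),
                               call. = FALSE))
    scores[[wl]] <- tryCatch(
      score_submissions(submissions, consensus[[wl]]),
      error = function(e) stop("pipeline stage 'scores' (window '", w$label,
                               "'): ", conditionMessage(e), call. = FALSE))
    rep_w <- tryCatch(
      iqr_outliers(submissions, w, ...),
      error = function(e) stop("pipeline stage 'outliers' (window '",
                               w$label, "'): ", conditionMessage(e),
                               call. = FALSE))
    rep_w$sensitivity_ok <- sensitivity_check(rep_w)
    outliers[[wl]] <- rep_w
  }
  all_scores <- do.call(rbind, scores)
  rownames(all_scores) <- NULL
  class(all_scores) <- c("score_records", "data.frame")
  structure(list(
    consensus = consensus,
    scores = all_scores,
    outliers = outliers,
    summary = summary_table(all_scores),
    windows = windows
  ), class = "radon_pt_results")
}

#' Per-class performance summary
#'
#' For every (device class, window) pair, the percentage of results with
#' `|D| <= 10%`, `|D| <= 20%`, and in each of the three zeta and z bands
#' (`<= 2.0`, between 2.0 and 3.0, `>= 3.0`). Denominators (the number of
#' results in each class/window cell) are always reported explicitly. Within
#' each cell the three zeta bands sum to 100% (up to rounding when rendered),
#' as do the three z bands, and the `|D| <= 10%` percentage can never exceed
#' the `|D| <= 20%` one.
#'
#' @param scores score records from [score_submissions()] (possibly several
#'   windows stacked).
#' @return data.frame with one row per (device_kind, window): `device_kind`,
#'   `window`, `n`, `D_le_10`, `D_le_20`, `zeta_le_2`, `zeta_2_3`,
#'   `zeta_ge_3`, `z_le_2`, `z_2_3`, `z_ge_3` (percentages, full precision).
#' @export
summary_table <- function(scores) {
  stopifnot(all(c("device_kind", "window", "D_percent", "zeta", "z")
                %in% names(scores)))
  cells <- unique(scores[c("device_kind", "window")])
  cells <- cells[order(cells$device_kind, cells$window), , drop = FALSE]
  pct <- function(x) 100 * mean(x)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- scores$device_kind == cells$device_kind[i] &
      scores$window == cells$window[i]
    s <- scores[sel, , drop = FALSE]
    data.frame(
      device_kind = cells$device_kind[i],
      window = cells$window[i],
      n = nrow(s),
      D_le_10 = pct(abs(s$D_percent) <= 10),
      D_le_20 = pct(abs(s$D_percent) <= 20),
      zeta_le_2 = pct(abs(s$zeta) <= 2),
      zeta_2_3 = pct(abs(s$zeta) > 2 & abs(s$zeta) < 3),
      zeta_ge_3 = pct(abs(s$zeta) >= 3),
      z_le_2 = pct(abs(s$z) <= 2),
      z_2_3 = pct(abs(s$z) > 2 & abs(s$z) < 3),
      z_ge_3 = pct(abs(s$z) >= 3),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Consensus report table
#'
#' One row per window with the reference parameters, in the layout of a
#' campaign report: window, `E_ref`, `u(E_ref)`, `sigma_p`, `s*`, `p`.
#' `digits = 0` (the default) rounds to integers as campaign reports print
#' them (round-half-even); `digits = NA` keeps full precision.
#'
#' @param consensus named list of `consensus_result` objects (e.g.
#'   `results$consensus` from [run_pipeline()]).
#' @param digits integer or `NA` for no rounding.
#' @return data.frame with columns `window`, `E_ref`, `u_E_ref`, `sigma_p`,
#'   `s_star`, `p`.
#' @export
consensus_table <- function(consensus, digits = 0) {
  rnd <- function(x) if (is.na(digits)) x else round(x, digits)
  out <- do.call(rbind, lapply(consensus, function(cr) data.frame(
    window = cr$window_label,
    E_ref = rnd(cr$e_ref),
    u_E_ref = rnd(cr$u_e_ref),
    sigma_p = rnd(cr$sigma_p),
    s_star = rnd(cr$s_star),
    p = cr$p,
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out
}

#' @export
print.radon_pt_results <- function(x, ...) {
  cat("Radon proficiency-test results\n\n")
  print(consensus_table(x$consensus))
  cat("\nSummary (% of results per class and window):\n")
  s <- x$summary
  s[4:11] <- lapply(s[4:11], round)
  print(s)
  for (wl in names(x$outliers)) {
    oc <- x$outliers[[wl]]$outlier_codes
    cat(sprintf("\n%s outliers: %s (consensus insensitive to removal: %s)",
                wl, if (length(oc)) paste(oc, collapse = ", ") else "none",
                x$outliers[[wl]]$sensitivity_ok))
  }
  cat("\n")
  invisible(x)
}

#' Render pipeline results to files
#'
#' Writes the consensus table (report layout, integer precision), the
#' summary table (percentages rounded to integers), and the full score
#' records. `"csv"` writes three CSV files; `"json"` writes one JSON file
#' keeping full precision; `"markdown"` writes one Markdown file with pipe
#' tables.
#'
#' @param results a `radon_pt_results` object from [run_pipeline()].
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(results, format = c("csv", "json", "markdown"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(results, "radon_pt_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  cons_print <- consensus_table(results$consensus, digits = 0)
  summ_print <- results$summary
  summ_print[4:11] <- lapply(summ_print[4:11], round)
  if (format == "csv") {
    f1 <- file.path(dir, "consensus.csv")
    f2 <- file.path(dir, "summary.csv")
    f3 <- file.path(dir, "scores.csv")
    utils::write.csv(cons_print, f1, row.names = FALSE, quote = FALSE)
    utils::write.csv(summ_print, f2, row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(results$scores), f3, row.names = FALSE,
                     quote = FALSE)
    files <- c(f1, f2, f3)
  } else if (format == "json") {
    f <- file.path(dir, "report.json")
    payload <- list(
      consensus = consensus_table(results$consensus, digits = NA),
      summary = results$summary,
      scores = as.data.frame(results$scores),
      outliers = lapply(results$outliers, function(o)
        o[c("window_label", "q1", "q3", "iqr", "lower_fence", "upper_fence",
            "outlier_codes", "e_ref_all", "u_e_ref_all",
            "e_ref_without_outliers", "u_e_ref_without_outliers",
            "sensitivity_ok")])
    )
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- f
  } else {
    f <- file.path(dir, "report.md")
    lines <- c("# Proficiency-test report", "",
               "## Reference parameters", "", md_table(cons_print), "",
               "## Performance summary (%)", "", md_table(summ_print), "")
    for (wl in names(results$outliers)) {
      oc <- results$outliers[[wl]]$outlier_codes
      lines <- c(lines, sprintf("Outliers (%s): %s", wl,
        if (length(oc)) paste(oc, collapse = ", ") else "none"))
    }
    writeLines(lines, f)
    files <- f
  }
  invisible(files)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
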
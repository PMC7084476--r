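#' Relative percentage difference D(%)
#'
#' `D = 100 * (E_i - E_ref) / E_ref`: the participant's deviation from the
#' assigned value, in percent of the assigned value.
#'
#' @param e_i participant result(s).
#' @param e_ref assigned value (> 0).
#' @return numeric, percent.
#' @examples
#' relative_difference(391.6, 356) # +10
#' @export
relative_difference <- function(e_i, e_ref) {
  if (!is.numeric(e_ref) || any(e_ref <= 0)) {
    stop("'e_ref' must be > 0", call. = FALSE)
  }
  100 * (e_i - e_ref) / e_ref
}

#' Zeta score
#'
#' `zeta = (E_i - E_ref) / sqrt(u(E_i)^2 + u(E_ref)^2)`: the deviation in
#' units of the combined standard uncertainty of the participant and the
#' assigned value. It diagnoses whether the participant's declared
#' uncertainty budget is realistic.
#'
#' With zero combined uncertainty the score is undefined when `E_i != E_ref`
#' (error) and 0 by limit convention when `E_i == E_ref`.
#'
#' @param e_i participant result(s).
#' @param u_e_i participant standard uncertainty (k = 1), >= 0.
#' @param e_ref assigned value.
#' @param u_e_ref standard uncertainty of the assigned value, >= 0.
#' @return numeric, dimensionless.
#' @examples
#' zeta_score(380, 10, 356, 8) # 24 / sqrt(164)
#' @export
zeta_score <- function(e_i, u_e_i, e_ref, u_e_ref) {
  if (any(u_e_i < 0) || any(u_e_ref < 0)) {
    stop("uncertainties must be >= 0", call. = FALSE)
  }
  denom <- sqrt(u_e_i^2 + u_e_ref^2)
  num <- e_i - e_ref
  out <- num / denom # recycles to the common length
  zero_denom <- rep_len(denom == 0, length(out))
  zero_num <- rep_len(num == 0, length(out))
  if (any(zero_denom & !zero_num)) {
    stop("zeta score undefined: zero combined uncertainty with E_i != E_ref",
         call. = FALSE)
  }
  out[zero_denom] <- 0
  out
}

#' z-score
#'
#' `z = (E_i - E_ref) / sigma_p`, where sigma_p is the standard deviation for
#' proficiency assessment (here a stated fraction of the assigned value: 20%
#' for the first exposure window, 10% for the second).
#'
#' @param e_i participant result(s).
#' @param e_ref assigned value.
#' @param sigma_p standard deviation for proficiency assessment (> 0).
#' @return numeric, dimensionless.
#' @examples
#' z_score(427.2, 356, 71.2) # 1
#' @export
z_score <- function(e_i, e_ref, sigma_p) {
  if (!is.numeric(sigma_p) || any(sigma_p <= 0)) {
    stop("'sigma_p' must be > 0", call. = FALSE)
  }
  (e_i - e_ref) / sigma_p
}

#' Classify a zeta or z score
#'
#' Standard proficiency-testing bands: `|score| <= 2.0` is satisfactory,
#' `2.0 < |score| < 3.0` signals a problem, `|score| >= 3.0` is not
#' satisfactory. The boundaries follow the printed inequalities: exactly 2.0
#' is satisfactory, exactly 3.0 is not satisfactory.
#'
#' @param score numeric vector of scores.
#' @return character vector: `"satisfactory"`, `"problem"`,
#'   `"not_satisfactory"`.
#' @export
classify_score <- function(score) {
  a <- abs(score)
  ifelse(a <= 2.0, "satisfactory",
         ifelse(a < 3.0, "problem", "not_satisfactory"))
}

#' Joint zeta/z interpretation
#'
#' Maps the pair of classifications to the standard action guidance. The
#' published guidance table has only satisfactory / not-satisfactory rows;
#' the intermediate "problem" band (2.0 < |score| < 3.0) inherits the
#' not-satisfactory action of the corresponding row, and the result is
#' flagged `borderline` so reports can still count the three bands
#' separately.
#'
#' Actions:
#' \describe{
#'   \item{`no_action`}{both satisfactory: the result is good.}
#'   \item{`claimed_uncertainty_too_low`}{zeta not satisfactory, z
#'     satisfactory: the result meets the comparison requirement but the
#'     declared uncertainty is too small.}
#'   \item{`result_not_compliant`}{zeta satisfactory, z not satisfactory: the
#'     uncertainty assessment is accurate but the result does not meet the
#'     comparison requirement.}
#'   \item{`complete_revaluation`}{both not satisfactory: the result is
#'     biased; a complete revaluation should be performed.}
#' }
#'
#' @param zeta_class,z_class classification strings from [classify_score()]
#'   (vectors, recycled to common length).
#' @return data.frame with columns `action` and `borderline` (logical: TRUE
#'   when either input was in the "problem" band).
#' @export
joint_interpretation <- function(zeta_class, z_class) {
  valid <- c("satisfactory", "problem", "not_satisfactory")
  if (!all(zeta_class %in% valid) || !all(z_class %in% valid)) {
    stop("classes must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(zeta_class), length(z_class))
  zeta_class <- rep_len(zeta_class, n)
  z_class <- rep_len(z_class, n)
  zeta_bad <- zeta_class != "satisfactory"
  z_bad <- z_class != "satisfactory"
  action <- ifelse(!zeta_bad & !z_bad, "no_action",
            ifelse(zeta_bad & !z_bad, "claimed_uncertainty_too_low",
            ifelse(!zeta_bad & z_bad, "result_not_compliant",
                   "complete_revaluation")))
  data.frame(action = action,
             borderline = zeta_class == "problem" | z_class == "problem")
}

#' Score all submissions of one window against its consensus
#'
#' Computes D(%), zeta and z for every submission in the window, classifies
#' both scores and attaches the joint action. Scores are computed from the
#' full-precision consensus values, never from rounded report values, so a
#' result sitting near a band edge is classified by its true score.
#'
#' @param submissions submissions data.frame (see [as_submissions()]).
#' @param consensus a `consensus_result` from [consensus_for_window()].
#' @return data.frame of class `c("score_records", "data.frame")` with
#'   columns `code`, `window`, `device_kind`, `D_percent`, `zeta`, `z`,
#'   `zeta_class`, `z_class`, `action`, `borderline`.
#' @export
score_submissions <- function(submissions, consensus) {
  stopifnot(inherits(consensus, "consensus_result"))
  rows <- submissions[submissions$window == consensus$window_label, ,
                      drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no submissions for window '", consensus$window_label, "'",
         call. = FALSE)
  }
  d <- relative_difference(rows$exposure_kBqm3h, consensus$e_ref)
  zeta <- zeta_score(rows$exposure_kBqm3h, rows$u_k1_kBqm3h,
                     consensus$e_ref, consensus$u_e_ref)
  z <- z_score(rows$exposure_kBqm3h, consensus$e_ref, consensus$sigma_p)
  zc <- classify_score(zeta)
  zzc <- classify_score(z)
  act <- joint_interpretation(zc, zzc)
  out <- data.frame(
    code = rows$code,
    window = rows$window,
    device_kind = device_kind(rows$code),
    D_percent = d,
    zeta = zeta,
    z = z,
    zeta_class = zc,
    z_class = zzc,
    action = act$action,
    borderline = act$borderline,
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_records", "data.frame")
  out
}
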
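#' Published reference parameters of the 2018 LNR field intercomparison
#'
#' The reference parameters published for the two exposure windows of the
#' November 2018 indoor-radon field intercomparison at the Laboratory of
#' Natural Radiation (45 and 41 participant results): the consensus assigned
#' value `E_ref`, the robust standard deviation `s_star` from Algorithm A,
#' the number of results `p`, and the sigma_p fraction used for proficiency
#' assessment (20% of `E_ref` for E1, 10% for E2). All exposures in
#' kBq m^-3 h. The participant-level results behind these numbers were never
#' published, so the row is useful as an input for consistency checks (e.g.
#' re-deriving `u(E_ref)` with [uncertainty_of_reference()]), not as a
#' recomputable consensus.
#'
#' @return data.frame with columns `window`, `E_ref`, `s_star`, `p`,
#'   `sigma_p_fraction`.
#' @examples
#' ref <- lnr2018_reference()
#' uncertainty_of_reference(ref$s_star, ref$p) # 8.01, 13.28
#' @export
lnr2018_reference <- function() {
  data.frame(
    window = c("E1", "E2"),
    E_ref = c(356, 1014),
    s_star = c(43, 68),
    p = c(45L, 41L),
    sigma_p_fraction = c(0.20, 0.10),
    stringsAsFactors = FALSE
  )
}
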
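# Independent, deliberately literal transcription of the iterative robust
# estimator (median/MAD start, winsorise at +/- 1.5 s*, rescaled mean and SD),
# written step by step with an explicit per-item loop. Used only as an oracle
# against algorithm_a(); kept free of any code shared with the implementation.
oracle_robust <- function(E, tol = 1e-12, max_iter = 2000L) {
  p <- length(E)
  e_ref <- median(E)
  devs <- abs(E - e_ref)
  s_star <- 1.483 * median(devs)
  if (s_star == 0) return(list(e_ref = e_ref, s_star = 0))
  for (it in seq_len(max_iter)) {
    delta <- 1.5 * s_star
    e_star <- numeric(p)
    for (i in seq_len(p)) {
      if (E[i] < e_ref - delta) {
        e_star[i] <- e_ref - delta
      } else if (E[i] > e_ref + delta) {
        e_star[i] <- e_ref + delta
      } else {
        e_star[i] <- E[i]
      }
    }
    m <- sum(e_star) / p
    sq <- 0
    for (i in seq_len(p)) sq <- sq + (e_star[i] - m)^2
    s_new <- 1.134 * sqrt(sq / (p - 1))
    moved_e <- abs(m - e_ref)
    moved_s <- abs(s_new - s_star)
    e_ref <- m
    old_s <- s_star
    s_star <- s_new
    if (moved_e < tol * max(abs(e_ref), 1e-300) &&
        moved_s < tol * max(old_s, 1e-300)) break
    if (s_star == 0) break
  }
  list(e_ref = e_ref, s_star = s_star)
}
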
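# Small in-code fixtures shared across test files.

fixture_submissions <- function() {
  as_submissions(data.frame(
    code = c("L01P1", "L02P1", "L03A1", "L01P1", "L02P1", "L03A1"),
    window = c("E1", "E1", "E1", "E2", "E2", "E2"),
    exposure_kBqm3h = c(350, 360, 355, 1000, 1020, 1010),
    u_k1_kBqm3h = c(12, 11, 5, 30, 28, 12)
  ))
}

# cache default campaigns so seed sweeps are generated once per test run
campaign_cache <- new.env(parent = emptyenv())
cached_campaign <- function(seed) {
  key <- as.character(seed)
  if (is.null(campaign_cache[[key]])) {
    campaign_cache[[key]] <- generate_campaign(seed = seed)
  }
  campaign_cache[[key]]
}
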
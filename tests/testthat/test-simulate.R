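test_that("default chamber dynamics hit the campaign anchors", {
  sim <- simulate_chamber(seed = 1)
  te <- sim$true_exposures
  # true exposures land near the campaign's consensus magnitudes
  expect_lt(abs(te[["E1"]] - 356) / 356, 0.20)
  expect_lt(abs(te[["E2"]] - 1014) / 1014, 0.20)
  # frozen regression values of the default dynamics
  expect_equal(te[["E1"]], 355.8827, tolerance = 1e-6)
  expect_equal(te[["E2"]], 954.5043, tolerance = 1e-6)
  conc <- sim$noiseless$concentration_kBqm3
  expect_equal(conc[14], 30, tolerance = 1e-4)    # end of E1: ~30 kBq m-3
  expect_lt(tail(conc, 1) * exp(-0.048), 2)       # end of E2: < 2 kBq m-3
  expect_gte(min(conc), 0.3)                      # spans ~0.5-30 kBq m-3
  expect_lte(max(conc), 32)
})

test_that("noiseless instant-rise no-decay chamber is a constant plateau", {
  p <- chamber_params(plateau_kBqm3 = 20, baseline_kBqm3 = 20,
                      rise_rate_per_h = 1e6, decay_rate_per_h = 0,
                      noise_cv = 0)
  sim <- simulate_chamber(p, seed = 1)
  expect_true(all(abs(sim$series$concentration_kBqm3 - 20) < 1e-9))
  expect_equal(sim$true_exposures[["E1"]], 20 * 13)
  expect_equal(sim$true_exposures[["E2"]], 20 * 70)
})

test_that("a window starting before the campaign is an error", {
  w <- list(E1 = default_windows()$E1,
            W = exposure_window("W", "2018-11-01 00:00", "2018-11-02 00:00",
                                0.2))
  expect_error(simulate_chamber(windows = w), "before the campaign")
})

test_that("noiseless passive group reports the truth with zero uncertainty", {
  m <- device_model("passive_group", reporting_cv = 0)
  s <- simulate_passive_group(356, m, seed = 1)
  expect_equal(s$exposure_kBqm3h, 356)
  expect_equal(s$u_k1_kBqm3h, 0)
})

test_that("degassing factor 1.6 inflates the expected report by 60%", {
  m <- device_model("passive_group", degassing_factor = 1.6)
  reps <- vapply(1:400, function(s)
    simulate_passive_group(356, m, seed = s)$exposure_kBqm3h, numeric(1))
  # Monte-Carlo error of the mean: 10%/sqrt(10)/sqrt(400) ~ 0.16%
  expect_equal(mean(reps), 569.6, tolerance = 0.01)
})

test_that("the reported uncertainty follows the standard-error law", {
  m <- device_model("passive_group", n_detectors = 10, reporting_cv = 0.10)
  us <- vapply(1:300, function(s) {
    r <- simulate_passive_group(356, m, seed = s)
    r$u_k1_kBqm3h / r$exposure_kBqm3h
  }, numeric(1))
  expect_equal(mean(us), 0.10 / sqrt(10), tolerance = 0.05)
})

test_that("a passive group needs at least two detectors", {
  expect_error(device_model("passive_group", n_detectors = 1), "at least 2")
})

test_that("active-monitor counting noise scales inversely with sensitivity", {
  sim <- simulate_chamber(seed = 3)
  w <- default_windows()$E1
  hi <- device_model("active_monitor", sensitivity_cpm_per_kBqm3 = 50)
  lo <- device_model("active_monitor", sensitivity_cpm_per_kBqm3 = 0.1)
  r_hi <- simulate_active_monitor(sim$series, hi, w, seed = 7)
  r_lo <- simulate_active_monitor(sim$series, lo, w, seed = 7)
  res_hi <- r_hi$series$concentration_kBqm3 - sim$series$concentration_kBqm3
  res_lo <- r_lo$series$concentration_kBqm3 - sim$series$concentration_kBqm3
  expect_gt(sd(res_lo), 5 * sd(res_hi))
  # at 30 kBq m-3 a 50 cpm/(kBq m-3) monitor counts 90000 per hour:
  # relative counting error ~ 1/sqrt(counts) < 1%
  peak <- which.max(sim$series$concentration_kBqm3)
  lambda <- 50 * sim$series$concentration_kBqm3[peak] * 60
  expect_lt(1 / sqrt(lambda), 0.01)
})

test_that("an ideal (infinite-sensitivity) monitor reproduces the truth exactly", {
  sim <- simulate_chamber(seed = 4)
  m <- device_model("active_monitor", sensitivity_cpm_per_kBqm3 = Inf,
                    u_cal_declared_cv = 0)
  r <- simulate_active_monitor(sim$series, m, default_windows()$E1, seed = 1)
  expect_equal(r$series$concentration_kBqm3, sim$series$concentration_kBqm3)
  expect_equal(r$submission$exposure_kBqm3h,
               integrate_exposure(sim$series, default_windows()$E1))
  expect_equal(r$submission$u_k1_kBqm3h, 0)
})

test_that("a default campaign has the expected bookkeeping", {
  camp <- cached_campaign(1)
  expect_equal(sum(camp$submissions$window == "E1"), 45)
  expect_equal(sum(camp$submissions$window == "E2"), 41)
  expect_equal(nrow(camp$truth$devices), 45)
  expect_equal(length(camp$truth$contaminated_codes), 5)
  expect_true(all(device_kind(camp$truth$contaminated_codes) == "passive"))
  expect_false(any(duplicated(paste(camp$submissions$code,
                                    camp$submissions$window))))
})

test_that("the same seed reproduces a campaign bit for bit", {
  a <- generate_campaign(seed = 77)
  b <- generate_campaign(seed = 77)
  expect_identical(a$submissions, b$submissions)
  expect_identical(a$monitor_series, b$monitor_series)
  expect_identical(a$truth$devices, b$truth$devices)
  c2 <- generate_campaign(seed = 78)
  expect_false(identical(a$submissions, c2$submissions))
})

test_that("campaign generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_campaign(seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("zero contamination leaves every degassing factor at one", {
  camp <- generate_campaign(contaminated_fraction = 0, seed = 5)
  expect_true(all(camp$truth$devices$degassing_factor == 1))
  expect_equal(camp$truth$contaminated_codes, character(0))
  expect_error(generate_campaign(contaminated_fraction = 1.2, seed = 1),
               "0, 1")
  expect_error(generate_campaign(seed = "no"), "seed")
})

test_that("campaign truth equals the noiseless chamber integral", {
  camp <- cached_campaign(2)
  for (wl in names(camp$windows)) {
    expect_equal(camp$truth$true_exposures[[wl]],
                 integrate_exposure(camp$truth$chamber$noiseless,
                                    camp$windows[[wl]]))
  }
})
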
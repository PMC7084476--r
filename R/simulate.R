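#' Chamber dynamics parameters
#'
#' Parametric rise-plateau-decay model of the radon concentration in the
#' exposure room: a saturating exponential rise from `baseline` towards
#' `plateau` during the first exposure window, followed by an exponential
#' decay once the room is opened at `decay_start`. Hourly samples receive
#' multiplicative lognormal jitter of coefficient of variation `noise_cv`
#' emulating environmental fluctuation.
#'
#' The defaults were fixed once against the campaign they emulate: the
#' concentration reaches ~30 kBq m^-3 at the end of the 13 h first window,
#' falls below 2 kBq m^-3 by the end of the 70 h second window, spans roughly
#' 0.5-30 kBq m^-3 overall, and integrates (noiselessly, left-rectangular
#' rule) to true exposures of 355.9 and 954.5 kBq m^-3 h for the two windows.
#'
#' @param plateau_kBqm3 asymptotic concentration during the rise phase
#'   (default 30).
#' @param baseline_kBqm3 concentration at the campaign start (default 0.5).
#' @param rise_rate_per_h rise rate constant (default 2.0 h^-1).
#' @param decay_rate_per_h decay rate constant after `decay_start_h`
#'   (default 0.048 h^-1).
#' @param decay_start_h hours after campaign start at which decay begins
#'   (default 13, the end of the first window).
#' @param noise_cv coefficient of variation of the hourly multiplicative
#'   jitter (default 0.03).
#' @return list of class `chamber_params`.
#' @export
chamber_params <- function(plateau_kBqm3 = 30, baseline_kBqm3 = 0.5,
                           rise_rate_per_h = 2.0, decay_rate_per_h = 0.048,
                           decay_start_h = 13, noise_cv = 0.03) {
  stopifnot(plateau_kBqm3 > 0, baseline_kBqm3 >= 0, rise_rate_per_h > 0,
            decay_rate_per_h >= 0, decay_start_h > 0, noise_cv >= 0)
  structure(list(plateau_kBqm3 = plateau_kBqm3,
                 baseline_kBqm3 = baseline_kBqm3,
                 rise_rate_per_h = rise_rate_per_h,
                 decay_rate_per_h = decay_rate_per_h,
                 decay_start_h = decay_start_h,
                 noise_cv = noise_cv),
            class = "chamber_params")
}

# noiseless chamber concentration at t hours after campaign start
chamber_curve <- function(t, params) {
  rise <- params$plateau_kBqm3 +
    (params$baseline_kBqm3 - params$plateau_kBqm3) *
      exp(-params$rise_rate_per_h * t)
  c_ds <- params$plateau_kBqm3 +
    (params$baseline_kBqm3 - params$plateau_kBqm3) *
      exp(-params$rise_rate_per_h * params$decay_start_h)
  decay <- c_ds * exp(-params$decay_rate_per_h * (t - params$decay_start_h))
  ifelse(t < params$decay_start_h, rise, decay)
}

# lognormal draws with a given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  if (any(mean < 0)) stop("lognormal mean must be >= 0", call. = FALSE)
  sdlog <- sqrt(log1p(cv^2))
  out <- numeric(n)
  pos <- rep_len(mean, n) > 0
  out[pos] <- stats::rlnorm(sum(pos), log(rep_len(mean, n)[pos]) - sdlog^2 / 2,
                            sdlog)
  out
}

# run expr with a private RNG stream; NULL seed = use the current stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate the chamber concentration series
#'
#' Generates the hourly radon-concentration series covering all requested
#' exposure windows: the noiseless parametric curve (on which the true
#' exposures are computed) and the observed series with multiplicative
#' lognormal jitter. Deterministic given `seed`.
#'
#' @param params a [chamber_params()] object.
#' @param windows named list of [exposure_window()]s; all must share the
#'   campaign start and lie within the simulated span.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return list of class `chamber_sim`: `series` (observed
#'   [monitor_series()], code `"chamber"`), `noiseless` (same grid, no
#'   jitter), `true_exposures` (named numeric per window, from the noiseless
#'   series), `params`.
#' @export
simulate_chamber <- function(params = chamber_params(),
                             windows = default_windows(), seed = NULL) {
  stopifnot(inherits(params, "chamber_params"), length(windows) >= 1L)
  starts <- vapply(windows, function(w) as.numeric(w$start), numeric(1))
  ends <- vapply(windows, function(w) as.numeric(w$end), numeric(1))
  # the first window anchors t = 0 of the rise-plateau-decay dynamics
  t0 <- starts[1]
  if (any(starts < t0)) {
    stop("window(s) ", paste(names(windows)[starts < t0], collapse = ", "),
         " start before the campaign (the first window defines its start)",
         call. = FALSE)
  }
  n_hours <- ceiling((max(ends) - t0) / 3600)
  if (n_hours < 1) stop("windows span no full hour", call. = FALSE)
  t_h <- 0:(n_hours - 1)
  clean <- chamber_curve(t_h, params)
  noisy <- with_local_seed(seed, rlnorm_mean_cv(length(clean), clean,
                                                params$noise_cv))
  grid <- as.POSIXct(t0 + t_h * 3600, tz = "UTC", origin = "1970-01-01")
  noiseless <- monitor_series("chamber", grid, clean)
  series <- monitor_series("chamber", grid, noisy)
  true_exposures <- vapply(windows, function(w)
    integrate_exposure(noiseless, w), numeric(1))
  structure(list(series = series, noiseless = noiseless,
                 true_exposures = true_exposures, params = params),
            class = "chamber_sim")
}

#' Device response model
#'
#' Parameters of one participating device: a group of passive detectors or a
#' single active monitor.
#'
#' @param kind `"passive_group"` or `"active_monitor"`.
#' @param n_detectors number of passive detectors exposed per window
#'   (default 10; at least 2 so a standard error exists).
#' @param reporting_cv coefficient of variation of an individual passive
#'   detector reading (default 0.10).
#' @param calibration_bias multiplicative calibration factor of the device
#'   (default 1 = perfectly calibrated).
#' @param degassing_factor multiplicative exposure overestimation caused by
#'   radon adsorbed in the detector holder degassing after the window closes;
#'   1 = uncontaminated. Applies to passive groups only.
#' @param sensitivity_cpm_per_kBqm3 counting sensitivity of an active monitor
#'   (counts per minute at 1 kBq m^-3); drives Poisson counting noise.
#'   May be `Inf` for an ideal monitor.
#' @param u_cal_declared_cv calibration standard uncertainty an active
#'   monitor declares, as a fraction of its result (default 0.05).
#' @return list of class `device_model`.
#' @export
device_model <- function(kind = c("passive_group", "active_monitor"),
                         n_detectors = 10L, reporting_cv = 0.10,
                         calibration_bias = 1, degassing_factor = 1,
                         sensitivity_cpm_per_kBqm3 = 50,
                         u_cal_declared_cv = 0.05) {
  kind <- match.arg(kind)
  stopifnot(reporting_cv >= 0, calibration_bias > 0, degassing_factor >= 1,
            sensitivity_cpm_per_kBqm3 > 0, u_cal_declared_cv >= 0)
  if (kind == "passive_group" && n_detectors < 2L) {
    stop("a passive group needs at least 2 detectors (no standard error ",
         "of the mean otherwise)", call. = FALSE)
  }
  structure(list(kind = kind, n_detectors = as.integer(n_detectors),
                 reporting_cv = reporting_cv,
                 calibration_bias = calibration_bias,
                 degassing_factor = degassing_factor,
                 sensitivity_cpm_per_kBqm3 = sensitivity_cpm_per_kBqm3,
                 u_cal_declared_cv = u_cal_declared_cv),
            class = "device_model")
}

#' Simulate one passive-detector group result
#'
#' Draws `n_detectors` individual exposure readings as lognormal with
#' arithmetic mean `true_exposure x calibration_bias x degassing_factor +
#' storage background` and coefficient of variation `reporting_cv`, plus a
#' matched set of transit detectors seeing only the storage background
#' (storage area below 10 Bq m^-3, so the contribution is ~0.2 per mil of the
#' first-window exposure). The reported exposure is the exposed-group mean
#' minus the transit mean; the reported k = 1 uncertainty is the combined
#' standard error of the two means.
#'
#' @param true_exposure true exposure over the window, kBq m^-3 h.
#' @param model a [device_model()] with kind `"passive_group"`.
#' @param code participant code for the emitted submission row.
#' @param window_label window label for the emitted submission row.
#' @param storage_Bqm3 radon level of the storage area (default 5 Bq m^-3).
#' @param storage_hours time spent in storage before sealing (default 48 h).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return one-row submissions data.frame (`code`, `window`,
#'   `exposure_kBqm3h`, `u_k1_kBqm3h`) with the individual detector readings
#'   attached as attribute `"detectors"`.
#' @export
simulate_passive_group <- function(true_exposure, model,
                                   code = "L01P1", window_label = "E1",
                                   storage_Bqm3 = 5, storage_hours = 48,
                                   seed = NULL) {
  stopifnot(inherits(model, "device_model"), model$kind == "passive_group",
            true_exposure >= 0)
  b <- storage_Bqm3 / 1000 * storage_hours # storage background, kBq m^-3 h
  mu <- true_exposure * model$calibration_bias * model$degassing_factor + b
  with_local_seed(seed, {
    det <- rlnorm_mean_cv(model$n_detectors, mu, model$reporting_cv)
    transit <- rlnorm_mean_cv(model$n_detectors, b, model$reporting_cv)
    exposure <- max(0, mean(det) - mean(transit))
    u <- sqrt(stats::var(det) / model$n_detectors +
                stats::var(transit) / model$n_detectors)
    out <- data.frame(code = code, window = window_label,
                      exposure_kBqm3h = exposure, u_k1_kBqm3h = u,
                      stringsAsFactors = FALSE)
    attr(out, "detectors") <- det
    out
  })
}

#' Simulate one active-monitor series and result
#'
#' The monitor counts radon decays hour by hour: expected counts in an hour
#' are `sensitivity x concentration x 60 min`, the realised counts are
#' Poisson, and the monitor converts back through its (possibly miscalibrated)
#' response, reporting `calibration_bias x counts / (sensitivity x 60)` as
#' that hour's concentration. The submitted exposure is the integral of the
#' observed series over the window; its k = 1 uncertainty combines the
#' propagated counting statistics with the monitor's declared calibration
#' uncertainty. An infinite sensitivity reproduces the (calibrated) truth
#' exactly with zero counting uncertainty.
#'
#' @param chamber_series the concentration actually present in the room (a
#'   [monitor_series()], typically the observed series of
#'   [simulate_chamber()]).
#' @param model a [device_model()] with kind `"active_monitor"`.
#' @param window an [exposure_window()] covered by the series.
#' @param code participant code for the emitted rows.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return list: `series` (the observed [monitor_series()] under `code`) and
#'   `submission` (one-row submissions data.frame for the window).
#' @export
simulate_active_monitor <- function(chamber_series, model, window,
                                    code = "L01A1", seed = NULL) {
  stopifnot(inherits(model, "device_model"), model$kind == "active_monitor",
            inherits(window, "exposure_window"))
  obs <- with_local_seed(seed, observe_active(chamber_series, model, code))
  list(series = obs$series,
       submission = active_submission(obs, model, window))
}

# draw the monitor's full observed series once (Poisson counting per hour)
observe_active <- function(chamber_series, model, code) {
  s <- model$sensitivity_cpm_per_kBqm3
  conc_true <- chamber_series$concentration_kBqm3
  if (is.infinite(s)) {
    counts <- NULL
    obs <- model$calibration_bias * conc_true
  } else {
    counts <- stats::rpois(length(conc_true), s * conc_true * 60)
    obs <- model$calibration_bias * counts / (s * 60)
  }
  list(series = monitor_series(code, chamber_series$timestamp, obs),
       counts = counts)
}

# submission for one window, read off an observed active series
active_submission <- function(obs, model, window) {
  s <- model$sensitivity_cpm_per_kBqm3
  exposure <- integrate_exposure(obs$series, window)
  if (is.infinite(s)) {
    u_counting <- 0
  } else {
    t <- as.numeric(obs$series$timestamp)
    inside <- t >= as.numeric(window$start) & t < as.numeric(window$end)
    u_counting <- model$calibration_bias * sqrt(sum(obs$counts[inside])) /
      (s * 60)
  }
  u <- sqrt(u_counting^2 + (model$u_cal_declared_cv * exposure)^2)
  data.frame(code = obs$series$code[1], window = window$label,
             exposure_kBqm3h = exposure, u_k1_kBqm3h = u,
             stringsAsFactors = FALSE)
}

#' Campaign-level simulation settings
#'
#' Bundles every tunable of [generate_campaign()]. The defaults emulate the
#' November 2018 LNR field intercomparison: 23 passive groups of 10 detectors
#' each plus 22 active monitors over two overlapping windows, ~10%
#' individual-detector reporting noise, ~8% between-participant calibration
#' spread, active-monitor sensitivities spanning the 0.1-50 cpm per kBq m^-3
#' range of the deployed instruments, 4 participants missing from the second
#' window, and a contaminated passive subpopulation whose holder degassing
#' inflates the first-window exposure by a factor drawn uniformly from
#' [1.4, 2.6] (a +40% to +160% overestimation).
#'
#' @param chamber a [chamber_params()] object.
#' @param windows named list of [exposure_window()]s.
#' @param n_detectors passive detectors per group per window.
#' @param reporting_cv individual passive-detector coefficient of variation.
#' @param calibration_cv between-participant calibration spread (lognormal
#'   cv of the multiplicative calibration factor, both device classes).
#' @param degassing_range range of the uniform degassing factor applied to
#'   contaminated passive groups in the first window.
#' @param sensitivities_cpm pool of active-monitor sensitivities sampled with
#'   replacement (cpm at 1 kBq m^-3).
#' @param u_cal_declared_cv calibration uncertainty an active monitor
#'   declares (fraction of its result).
#' @param n_dropout_e2 number of participants (drawn at random) that report
#'   no second-window result.
#' @param storage_Bqm3,storage_hours storage background seen by passive and
#'   transit detectors.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(chamber = chamber_params(),
                            windows = default_windows(),
                            n_detectors = 10L, reporting_cv = 0.10,
                            calibration_cv = 0.08,
                            degassing_range = c(1.4, 2.6),
                            sensitivities_cpm = c(50, 20, 7, 1.8, 0.1),
                            u_cal_declared_cv = 0.05,
                            n_dropout_e2 = 4L,
                            storage_Bqm3 = 5, storage_hours = 48) {
  stopifnot(inherits(chamber, "chamber_params"), length(windows) >= 1L,
            n_detectors >= 2L, reporting_cv >= 0, calibration_cv >= 0,
            length(degassing_range) == 2L, degassing_range[1] >= 1,
            diff(degassing_range) >= 0, all(sensitivities_cpm > 0),
            n_dropout_e2 >= 0L)
  structure(list(chamber = chamber, windows = windows,
                 n_detectors = as.integer(n_detectors),
                 reporting_cv = reporting_cv, calibration_cv = calibration_cv,
                 degassing_range = degassing_range,
                 sensitivities_cpm = sensitivities_cpm,
                 u_cal_declared_cv = u_cal_declared_cv,
                 n_dropout_e2 = as.integer(n_dropout_e2),
                 storage_Bqm3 = storage_Bqm3, storage_hours = storage_hours),
            class = "campaign_config")
}

#' Generate a complete synthetic campaign
#'
#' Builds the chamber concentration series, assigns per-participant device
#' models (calibration factors, degassing contamination, monitor
#' sensitivities), and emits every submission for every window, together with
#' the full ground truth needed to test the analysis pipeline. All randomness
#' flows from the single `seed`; the same seed reproduces the campaign
#' bit-for-bit.
#'
#' Degassing contamination applies to the first window only: holder
#' adsorption matters when the room concentration is still high (~30
#' kBq m^-3) at the moment the window closes, whereas the second window ends
#' below 2 kBq m^-3, which suppresses the effect.
#'
#' @param n_passive number of passive-detector groups (default 23).
#' @param n_active number of active monitors (default 22).
#' @param contaminated_fraction fraction of passive groups affected by holder
#'   degassing (default 5/23, i.e. 5 groups at the default size).
#' @param config a [campaign_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `radon_campaign`: `submissions` (all windows,
#'   validated), `monitor_series` (stacked observed active-monitor series),
#'   `truth` (list: `chamber` [a `chamber_sim`], `true_exposures`, `devices`
#'   data.frame, `contaminated_codes`, `dropout_codes`), `windows`, `config`,
#'   `seed`.
#' @examples
#' camp <- generate_campaign(seed = 1)
#' table(camp$submissions$window)
#' @export
generate_campaign <- function(n_passive = 23L, n_active = 22L,
                              contaminated_fraction = 5 / 23,
                              config = campaign_config(), seed) {
  stopifnot(n_passive >= 0L, n_active >= 0L,
            inherits(config, "campaign_config"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("'seed' is mandatory: a campaign must be reproducible",
         call. = FALSE)
  }
  if (contaminated_fraction < 0 || contaminated_fraction > 1) {
    stop("'contaminated_fraction' must be in [0, 1]", call. = FALSE)
  }
  windows <- config$windows
  first_label <- names(windows)[1]
  with_local_seed(seed, {
    chamber <- simulate_chamber(config$chamber, windows, seed = NULL)
    p_codes <- if (n_passive > 0) format_code(seq_len(n_passive), "passive", 1)
               else character(0)
    a_codes <- if (n_active > 0) format_code(seq_len(n_active), "active", 1)
               else character(0)
    n_cont <- round(contaminated_fraction * n_passive)
    contaminated <- if (n_cont > 0) sort(sample(p_codes, n_cont))
                    else character(0)
    devices <- data.frame(
      code = c(p_codes, a_codes),
      device_kind = c(rep("passive", n_passive), rep("active", n_active)),
      calibration_bias = rlnorm_mean_cv(n_passive + n_active, 1,
                                        config$calibration_cv),
      degassing_factor = 1,
      sensitivity_cpm = NA_real_,
      contaminated = FALSE,
      stringsAsFactors = FALSE
    )
    devices$contaminated <- devices$code %in% contaminated
    devices$degassing_factor[devices$contaminated] <-
      stats::runif(n_cont, config$degassing_range[1], config$degassing_range[2])
    if (n_active > 0) {
      devices$sensitivity_cpm[devices$device_kind == "active"] <-
        sample(config$sensitivities_cpm, n_active, replace = TRUE)
    }
    all_codes <- devices$code
    dropout <- if (config$n_dropout_e2 > 0 && length(windows) > 1) {
      sort(sample(all_codes, min(config$n_dropout_e2, length(all_codes))))
    } else character(0)
    subs <- list()
    series_list <- list()
    for (i in seq_len(nrow(devices))) {
      dev <- devices[i, ]
      if (dev$device_kind == "passive") {
        for (wl in names(windows)) {
          if (wl != first_label && dev$code %in% dropout) next
          degas <- if (wl == first_label) dev$degassing_factor else 1
          model <- device_model("passive_group",
                                n_detectors = config$n_detectors,
                                reporting_cv = config$reporting_cv,
                                calibration_bias = dev$calibration_bias,
                                degassing_factor = degas)
          subs[[length(subs) + 1L]] <- simulate_passive_group(
            chamber$true_exposures[[wl]], model,
            code = dev$code, window_label = wl,
            storage_Bqm3 = config$storage_Bqm3,
            storage_hours = config$storage_hours, seed = NULL)
        }
      } else {
        # the instrument logs one continuous trace; both windows are read
        # off the same observed series
        model <- device_model("active_monitor",
                              calibration_bias = dev$calibration_bias,
                              sensitivity_cpm_per_kBqm3 = dev$sensitivity_cpm,
                              u_cal_declared_cv = config$u_cal_declared_cv)
        obs <- observe_active(chamber$series, model, dev$code)
        series_list[[length(series_list) + 1L]] <- obs$series
        for (wl in names(windows)) {
          if (wl != first_label && dev$code %in% dropout) next
          subs[[length(subs) + 1L]] <-
            active_submission(obs, model, windows[[wl]])
        }
      }
    }
    submissions <- as_submissions(do.call(rbind, subs), windows = windows)
    mon <- if (length(series_list)) {
      out <- do.call(rbind, series_list)
      rownames(out) <- NULL
      class(out) <- c("monitor_series", "data.frame")
      out
    } else NULL
    structure(list(
      submissions = submissions,
      monitor_series = mon,
      truth = list(chamber = chamber,
                   true_exposures = chamber$true_exposures,
                   devices = devices,
                   contaminated_codes = contaminated,
                   dropout_codes = dropout),
      windows = windows,
      config = config,
      seed = seed
    ), class = "radon_campaign")
  })
}

#' @export
print.radon_campaign <- function(x, ...) {
  kinds <- table(x$truth$devices$device_kind)
  cat(sprintf("Synthetic radon campaign (seed %s)\n", format(x$seed)))
  cat(sprintf("  %d passive groups, %d active monitors; %d submissions over %d window(s)\n",
              if ("passive" %in% names(kinds)) kinds[["passive"]] else 0L,
              if ("active" %in% names(kinds)) kinds[["active"]] else 0L,
              nrow(x$submissions), length(x$windows)))
  te <- x$truth$true_exposures
  cat("  true exposures:",
      paste(sprintf("%s = %.4g", names(te), te), collapse = ", "),
      "kBq m-3 h\n")
  if (length(x$truth$contaminated_codes)) {
    cat("  contaminated (degassing):",
        paste(x$truth$contaminated_codes, collapse = ", "), "\n")
  }
  invisible(x)
}
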
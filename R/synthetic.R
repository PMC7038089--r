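#' Scenario configuration for synthetic experiments
#'
#' Full generative truth for a synthetic two-stage experiment: exposure
#' model parameters, health-effect size, count scale and overdispersion,
#' confounder effect sizes and missingness. Presets are provided by
#' [scenario_preset].
#'
#' @param T_days number of days (>= 30).
#' @param S number of monitor sites (>= 2).
#' @param extent_km side of the square region monitors are scattered in.
#' @param max_dist_km if non-`NULL`, the network is rescaled so the maximum
#'   pairwise monitor distance equals this value.
#' @param start_date first calendar day.
#' @param exposure_truth an [exposure_params] generative truth.
#' @param pct_true true percent change in RR per 10 ug/m3 (converted to the
#'   per-unit log-RR coefficient `beta_true = log(1 + pct/100) / 10`).
#' @param lag_true lag (days) at which exposure acts on admissions.
#' @param baseline_rate marginal daily admission count scale.
#' @param nb_size negative-binomial size (smaller = more overdispersed).
#' @param seasonal_amplitude amplitude of the log-scale seasonal admission
#'   cycle (winter peak).
#' @param dow_log_effects 7 log-scale day-of-week effects (Mon..Sun),
#'   centred internally.
#' @param met_effect_scale named log-scale coefficients of the centred
#'   quadratic meteorology effects on admissions.
#' @param missing_pattern `list(type = "none")`,
#'   `list(type = "random", p = ...)` or
#'   `list(type = "block", site = i, start_frac = f)` (site `i` missing
#'   before day `ceiling(f * T)`, emulating a late-start monitor).
#' @param seed integer seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(T_days = 1096L, S = 9L, extent_km = 60,
                            max_dist_km = NULL,
                            start_date = as.Date("2014-01-01"),
                            exposure_truth = exposure_params(
                              mu = log(30), rho = 0.6, sigma_eps2 = 0.05,
                              sigma_z2 = 0.12, sigma_m2 = 0.04, phi = 25),
                            pct_true = 0, lag_true = 0L,
                            baseline_rate = 80, nb_size = 80,
                            seasonal_amplitude = 0.12,
                            dow_log_effects = c(0.04, 0.02, 0.01, 0, 0,
                                                -0.06, -0.08),
                            met_effect_scale = c(temperature = 0.03,
                                                 rh = 0.01, wind = 0.01,
                                                 pressure = 0.01),
                            missing_pattern = list(type = "none"),
                            seed = 1L) {
  if (T_days < 30L) stop("T_days must be >= 30")
  if (S < 2L) stop("S must be >= 2")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (nb_size <= 0) stop("nb_size must be positive")
  if (length(dow_log_effects) != 7L) stop("dow_log_effects must have length 7")
  cfg <- list(T_days = as.integer(T_days), S = as.integer(S),
              extent_km = extent_km, max_dist_km = max_dist_km,
              start_date = as.Date(start_date),
              exposure_truth = exposure_truth, pct_true = pct_true,
              beta_true = log(1 + pct_true / 100) / 10,
              lag_true = as.integer(lag_true),
              baseline_rate = baseline_rate, nb_size = nb_size,
              seasonal_amplitude = seasonal_amplitude,
              dow_log_effects = dow_log_effects,
              met_effect_scale = met_effect_scale,
              missing_pattern = missing_pattern, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a random monitor network
#'
#' Sites are placed uniformly in a square of side `extent_km`; optionally
#' the coordinates are rescaled so the maximum pairwise distance matches a
#' target (used to match the study networks' reported maximum monitor
#' separations).
#'
#' @param S number of sites (>= 2).
#' @param extent_km square side, km.
#' @param seed integer seed.
#' @param max_dist_km optional target maximum pairwise distance, km.
#' @return a [monitor_network].
#' @export
gen_network <- function(S, extent_km, seed, max_dist_km = NULL) {
  if (S < 2L) stop("S must be >= 2")
  set.seed(seed)
  xy <- cbind(stats::runif(S, 0, extent_km), stats::runif(S, 0, extent_km))
  if (!is.null(max_dist_km)) {
    d <- max(stats::dist(xy))
    xy <- xy * (max_dist_km / d)
  }
  monitor_network(sprintf("site%02d", seq_len(S)), xy)
}

#' Generate the latent exposure field
#'
#' Generative direction of the exposure model: stationary AR(1) latent
#' daily log level and spatially correlated site effects
#' `m ~ MVN(0, sigma_m2 * Sigma(phi))`.
#'
#' @param T_days number of days.
#' @param params an [exposure_params] truth.
#' @param network a [monitor_network].
#' @param seed integer seed.
#' @return list with `Z` (length T) and `m` (length S).
#' @export
gen_latent <- function(T_days, params, network, seed) {
  set.seed(seed)
  Z <- numeric(T_days)
  Z[1L] <- stats::rnorm(1L, params$mu,
                        sqrt(params$sigma_z2 / (1 - params$rho^2)))
  if (T_days > 1L) {
    e <- stats::rnorm(T_days - 1L, 0, sqrt(params$sigma_z2))
    for (t in 2:T_days)
      Z[t] <- params$mu + params$rho * (Z[t - 1L] - params$mu) + e[t - 1L]
  }
  R <- chol_spd(exp_correlation(network$D, params$phi))
  m <- sqrt(params$sigma_m2) *
    as.vector(crossprod(R, stats::rnorm(length(network$site_ids))))
  list(Z = Z, m = m)
}

#' Generate an observed pollutant panel from the latent field
#'
#' `W_st = exp(Z_t + m_s + N(0, sigma_eps2))`, with the requested
#' missingness mask applied. The block pattern makes one site entirely
#' missing before a start day, emulating a monitoring station established
#' partway through the study.
#'
#' @param Z latent daily log level.
#' @param m site effects.
#' @param sigma_eps2 measurement-error variance (log scale).
#' @param dates `Date` vector aligned with `Z`.
#' @param site_ids site labels aligned with `m`.
#' @param missing_pattern see [scenario_config].
#' @param seed integer seed.
#' @return a [pollution_panel].
#' @export
gen_panel <- function(Z, m, sigma_eps2, dates, site_ids,
                      missing_pattern = list(type = "none"), seed = 1L) {
  set.seed(seed)
  T_ <- length(Z); S <- length(m)
  W <- exp(outer(Z, m, "+") +
             matrix(stats::rnorm(T_ * S, 0, sqrt(sigma_eps2)), T_, S))
  mp <- missing_pattern
  if (identical(mp$type, "random")) {
    W[matrix(stats::runif(T_ * S) < mp$p, T_, S)] <- NA
  } else if (identical(mp$type, "block")) {
    start <- ceiling(mp$start_frac * T_)
    if (start >= 1L) W[seq_len(start), mp$site] <- NA
  } else if (!identical(mp$type, "none")) {
    stop("unknown missing_pattern type: ", mp$type)
  }
  pollution_panel(dates, site_ids, W)
}

#' Generate seasonal meteorology
#'
#' Annual sinusoids plus AR(1) noise with physically plausible constants
#' for a mid-latitude coastal/inland setting: temperature (mean 14 deg C,
#' amplitude 12, summer peak), relative humidity (mean 62%, summer peak,
#' clipped to [5, 100]), wind speed (mean 3 m/s, floor 0.2) and pressure
#' (mean 1013 hPa, winter peak).
#'
#' @param T_days number of days.
#' @param seed integer seed.
#' @param dates optional `Date` vector (defaults to consecutive days from
#'   2014-01-01); the seasonal phase uses the day of year.
#' @param amplitude_scale,noise_scale multipliers on the seasonal amplitudes
#'   and the AR(1) noise standard deviations (both 0 gives constant series).
#' @return a [meteorology_series].
#' @export
gen_meteorology <- function(T_days, seed, dates = NULL,
                            amplitude_scale = 1, noise_scale = 1) {
  if (is.null(dates)) dates <- as.Date("2014-01-01") + seq_len(T_days) - 1L
  set.seed(seed)
  doy <- as.integer(format(dates, "%j"))
  season <- amplitude_scale * cos(2 * pi * (doy - 197) / 365.25)  # peak mid-July
  ar1 <- function(n, rho, sd) {
    sd <- sd * noise_scale
    if (sd == 0) return(numeric(n))
    x <- numeric(n)
    e <- stats::rnorm(n, 0, sd)
    x[1L] <- e[1L] / sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1L] + e[t]
    x
  }
  temp <- 14 + 12 * season + ar1(T_days, 0.7, 2)
  rh <- pmin(100, pmax(5, 62 + 12 * season + ar1(T_days, 0.5, 8)))
  wind <- pmax(0.2, 3 + 0.5 * -season + ar1(T_days, 0.4, 0.8))
  pres <- 1013 - 8 * season + ar1(T_days, 0.6, 3)
  meteorology_series(dates, temp, rh, wind, pres)
}

#' Generate overdispersed daily admissions with known truth
#'
#' Log intensity = log(baseline) + beta_true * (C_{t-lag} - mean(C)) +
#' seasonal cycle + day-of-week effects + mild centred-quadratic meteorology
#' effects; every non-baseline term is centred to mean zero so
#' `baseline_rate` is the marginal count scale. Counts are negative
#' binomial (quasi-Poisson is not generative); sex and age strata are
#' binomial splits that re-sum exactly to the total.
#'
#' @param true_concentration daily concentration series C_t (ug/m3).
#' @param met a [meteorology_series] aligned with it.
#' @param config a [scenario_config].
#' @param seed integer seed.
#' @return list with `total` (an [admission_series]), `strata` (named list
#'   of the four stratum series), and `log_lambda` (the true log intensity).
#' @export
gen_admissions <- function(true_concentration, met, config, seed) {
  set.seed(seed)
  T_ <- length(true_concentration)
  dates <- met$date
  stopifnot(length(dates) == T_)
  Clag <- c(rep(true_concentration[1L], config$lag_true),
            true_concentration)[seq_len(T_)]
  ctr <- function(x) x - mean(x)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- ctr(config$seasonal_amplitude *
                    cos(2 * pi * (doy - 15) / 365.25))  # winter peak
  dow <- as.integer(format(dates, "%u"))
  dow_eff <- ctr(config$dow_log_effects)[dow]
  qeff <- function(x, a) ctr(a * ((x - mean(x)) / stats::sd(x))^2)
  mets <- qeff(met$temperature, config$met_effect_scale[["temperature"]]) +
    qeff(met$rh, config$met_effect_scale[["rh"]]) +
    qeff(met$wind, config$met_effect_scale[["wind"]]) +
    qeff(met$pressure, config$met_effect_scale[["pressure"]])
  log_lambda <- log(config$baseline_rate) + config$beta_true * ctr(Clag) +
    seasonal + dow_eff + mets
  if (any(log_lambda > 25)) stop("admission intensity overflow")
  lam <- exp(log_lambda)
  y <- stats::rnbinom(T_, size = config$nb_size, mu = lam)
  male <- stats::rbinom(T_, y, 0.55)
  old <- stats::rbinom(T_, y, 0.53)
  strata <- list(
    male = admission_series(dates, male, "male"),
    female = admission_series(dates, y - male, "female"),
    age65plus = admission_series(dates, old, "age65plus"),
    age65minus = admission_series(dates, y - old, "age65minus"))
  list(total = admission_series(dates, y, "total"), strata = strata,
       log_lambda = log_lambda)
}

#' Scenario presets
#'
#' `"jinan_like"`: 15 monitors with maximum separation 74.64 km, 1096 days
#' (2014-01-01 to 2016-12-31), baseline 291 admissions/day, NB size 150,
#' exposure level around 44 ug/m3, default true effect 2.647% per 10 ug/m3.
#' `"weihai_like"`: 9 monitors, 87.64 km, baseline 80/day, NB size 80,
#' exposure level around 30 ug/m3, default true effect 6.568%.
#' `"unit_test"`: tiny 60-day, 3-site scenario for fast tests.
#'
#' @param preset one of `"jinan_like"`, `"weihai_like"`, `"unit_test"`.
#' @param overrides named list of [scenario_config] arguments to override.
#' @param seed integer seed.
#' @return a [scenario_config].
#' @export
scenario_preset <- function(preset, overrides = list(), seed = 1L) {
  base <- switch(preset,
    jinan_like = list(
      T_days = 1096L, S = 15L, extent_km = 60, max_dist_km = 74.64,
      exposure_truth = exposure_params(mu = log(44), rho = 0.6,
                                       sigma_eps2 = 0.05, sigma_z2 = 0.12,
                                       sigma_m2 = 0.04, phi = 25),
      pct_true = 2.647, baseline_rate = 291, nb_size = 150),
    weihai_like = list(
      T_days = 1096L, S = 9L, extent_km = 70, max_dist_km = 87.64,
      exposure_truth = exposure_params(mu = log(30), rho = 0.6,
                                       sigma_eps2 = 0.05, sigma_z2 = 0.12,
                                       sigma_m2 = 0.04, phi = 25),
      pct_true = 6.568, baseline_rate = 80, nb_size = 80),
    unit_test = list(
      T_days = 60L, S = 3L, extent_km = 30, max_dist_km = NULL,
      exposure_truth = exposure_params(mu = log(20), rho = 0.5,
                                       sigma_eps2 = 0.05, sigma_z2 = 0.1,
                                       sigma_m2 = 0.04, phi = 10),
      pct_true = 2, baseline_rate = 50, nb_size = 100),
    stop("unknown preset: ", preset))
  args <- utils::modifyList(c(base, list(seed = seed)), overrides)
  do.call(scenario_config, args)
}

#' Generate a full synthetic scenario
#'
#' End-to-end generation of a monitor network, latent exposure field,
#' observed pollutant panel, meteorology and admissions (with strata), with
#' the generative truth kept alongside for recovery experiments. When `dir`
#' is given, writes `monitors.csv`, `pollution.csv`, `meteorology.csv`,
#' `admissions.csv` and `truth.json`.
#'
#' @param preset preset name (see [scenario_preset]) or a ready
#'   [scenario_config].
#' @param overrides named list of config overrides.
#' @param seed integer seed (distinct sub-seeds are derived per component).
#' @param dir optional output directory (created if needed).
#' @return list of class `scenario`: `config`, `network`, `truth` (list
#'   `Z`, `m`, `concentration`, `log_lambda`), `panel`, `met`,
#'   `admissions`, `strata`, and `files` (paths, when written).
#' @export
make_scenario <- function(preset = "unit_test", overrides = list(),
                          seed = 1L, dir = NULL) {
  cfg <- if (inherits(preset, "scenario_config")) preset
         else scenario_preset(preset, overrides, seed)
  dates <- cfg$start_date + seq_len(cfg$T_days) - 1L
  net <- gen_network(cfg$S, cfg$extent_km, seed = cfg$seed * 7L + 1L,
                     max_dist_km = cfg$max_dist_km)
  lat <- gen_latent(cfg$T_days, cfg$exposure_truth, net,
                    seed = cfg$seed * 7L + 2L)
  panel <- gen_panel(lat$Z, lat$m, cfg$exposure_truth$sigma_eps2, dates,
                     net$site_ids, cfg$missing_pattern,
                     seed = cfg$seed * 7L + 3L)
  met <- gen_meteorology(cfg$T_days, seed = cfg$seed * 7L + 4L,
                         dates = dates)
  conc <- exp(lat$Z)
  adm <- gen_admissions(conc, met, cfg, seed = cfg$seed * 7L + 5L)
  out <- list(config = cfg, network = net,
              truth = list(Z = lat$Z, m = lat$m, concentration = conc,
                           log_lambda = adm$log_lambda),
              panel = panel, met = met, admissions = adm$total,
              strata = adm$strata)
  class(out) <- "scenario"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(monitors = file.path(dir, "monitors.csv"),
               pollution = file.path(dir, "pollution.csv"),
               meteorology = file.path(dir, "meteorology.csv"),
               admissions = file.path(dir, "admissions.csv"),
               truth = file.path(dir, "truth.json"))
    write_monitors_csv(net, files[["monitors"]])
    write_pollution_csv(panel, files[["pollution"]])
    utils::write.csv(data.frame(date = as.character(met$date),
                                temperature = met$temperature, rh = met$rh,
                                wind = met$wind, pressure = met$pressure),
                     files[["meteorology"]], row.names = FALSE, quote = FALSE)
    adf <- do.call(rbind, lapply(c(list(out$admissions), out$strata),
      function(a) data.frame(date = as.character(a$dates), count = a$counts,
                             stratum = a$stratum)))
    utils::write.csv(adf, files[["admissions"]], row.names = FALSE,
                     quote = FALSE)
    tr <- list(config = cfg[setdiff(names(cfg), "exposure_truth")],
               exposure_truth = unclass(cfg$exposure_truth),
               Z = lat$Z, m = lat$m, concentration = conc)
    tr$config$start_date <- as.character(tr$config$start_date)
    jsonlite::write_json(tr, files[["truth"]], auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
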
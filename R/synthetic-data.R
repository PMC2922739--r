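# Synthetic daily weather, climate-scenario and mortality series with the
# statistical structure the analysis assumes: a sinusoidal annual
# temperature cycle with AR(1) residuals and summer heat episodes, a
# winter-high seasonal mortality cycle over a declining long-term trend
# (about 80 deaths/day in the early 1970s down to about 50), Poisson
# day-to-day noise, and multiplicative heat effects per stress grade.
# Scenario series add a constant warm bias and stepwise warming per
# future period, emulating regional-climate-model output.

#' Configuration of the synthetic-data generators
#'
#' @param start_year,end_year Calendar years covered (inclusive).
#' @param seed Master seed; each generator draws from its own stream
#'   derived from it, so adding one generator call never shifts another.
#' @param deaths_start,deaths_end Mean deaths/day at the start and end of
#'   the series; the trend between them is linear in time.
#' @param seasonal_amplitude Relative amplitude of the winter-high
#'   seasonal mortality cycle (fraction of the trend; maximum Jan 15).
#' @param grade_effects Named multiplicative mortality effects per stress
#'   grade (fractions; e.g. 0.13 = +13% on such days). Names must be the
#'   five grades of the grading module. Defaults are the all-causes
#'   sensitivities of the Vienna analysis, with slight heat stress sharing
#'   the below-moderate value.
#' @param met_mean_temp Annual-mean afternoon air temperature, degC.
#' @param met_annual_amplitude Amplitude of the annual temperature cycle,
#'   degC (maximum Jul 20).
#' @param met_resid_sd Standard deviation of the AR(1) temperature
#'   residual, degC.
#' @param ar1_coef Lag-1 autocorrelation of the temperature residual,
#'   in `[0, 1)`.
#' @param warming_per_period Scenario warming added cumulatively at each
#'   future period start, degC.
#' @param warm_bias Constant additive warm bias of the scenario ("model")
#'   series, degC.
#' @param lat,lon,altitude Station coordinates and altitude.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(start_year = 1970, end_year = 2007, seed = 1,
                             deaths_start = 80, deaths_end = 50,
                             seasonal_amplitude = 0.15,
                             grade_effects = c(acceptable = -0.018,
                                               slight = -0.018,
                                               moderate = 0.009,
                                               strong = 0.058,
                                               extreme = 0.130),
                             met_mean_temp = 16,
                             met_annual_amplitude = 14,
                             met_resid_sd = 3, ar1_coef = 0.7,
                             warming_per_period = 1, warm_bias = 1.5,
                             lat = 48.25, lon = 16.36, altitude = 198) {
  if (end_year <= start_year) stop("end_year must exceed start_year")
  if (deaths_start <= 0 || deaths_end <= 0) stop("deaths_* must be positive")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must be in [0, 1)")
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("seasonal_amplitude must be in [0, 1)")
  }
  if (!setequal(names(grade_effects), grade_levels)) {
    stop("grade_effects must be named by the five stress grades: ",
         paste(grade_levels, collapse = ", "))
  }
  cfg <- list(start_year = start_year, end_year = end_year, seed = seed,
              deaths_start = deaths_start, deaths_end = deaths_end,
              seasonal_amplitude = seasonal_amplitude,
              grade_effects = grade_effects,
              met_mean_temp = met_mean_temp,
              met_annual_amplitude = met_annual_amplitude,
              met_resid_sd = met_resid_sd, ar1_coef = ar1_coef,
              warming_per_period = warming_per_period,
              warm_bias = warm_bias,
              lat = lat, lon = lon, altitude = altitude)
  class(cfg) <- "generator_config"
  cfg
}

config_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", config$start_year)),
      as.Date(sprintf("%d-12-31", config$end_year)), by = "day")
}

#' Generate a daily afternoon meteorological series
#'
#' Temperature is an annual sinusoid (maximum Jul 20) plus an AR(1)
#' residual; relative humidity is anticorrelated with the temperature
#' anomaly and bounded to `[10, 100]`%; wind is gamma-distributed
#' (mean 3.5 m/s); cloud cover is binomial in octas with clearer skies
#' under warm anomalies. Reproducible for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return Data frame `date`, `ta`, `rh`, `wind`, `cloud`.
#' @export
generate_met_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream_seed(config$seed, "met", {
    dates <- config_dates(config)
    n <- length(dates)
    doy <- doy365(dates)
    seasonal <- config$met_mean_temp +
      config$met_annual_amplitude * cos(2 * pi * (doy - 201) / 365.25)
    resid <- numeric(n)
    innov_sd <- config$met_resid_sd * sqrt(1 - config$ar1_coef^2)
    innov <- stats::rnorm(n, 0, innov_sd)
    resid[1] <- stats::rnorm(1, 0, config$met_resid_sd)
    if (n > 1) {
      for (t in 2:n) resid[t] <- config$ar1_coef * resid[t - 1] + innov[t]
    }
    ta <- seasonal + resid
    rh <- clamp(stats::rnorm(n, 68 - 1.2 * resid, 8), 10, 100)
    wind <- stats::rgamma(n, shape = 4, scale = 0.875)
    cloud <- stats::rbinom(n, 8, stats::plogis(stats::qlogis(0.55) -
                                                 0.22 * resid))
    data.frame(date = dates, ta = ta, rh = rh, wind = wind, cloud = cloud)
  })
}

#' Generate a climate-scenario ("model") meteorological series
#'
#' Identical in construction to [generate_met_series()] (same stream for
#' the same seed), plus a constant warm bias on every temperature and a
#' cumulative warming increment at each future period start: days in the
#' i-th period get `(i - 1) * warming_per_period` degC. The perturbation
#' conserves vapour pressure, so relative humidity is recomputed (and
#' drops) as the air warms.
#'
#' @param config A [generator_config()] spanning the scenario years.
#' @param period_starts Increasing calendar years opening each period.
#' @return Data frame like [generate_met_series()], plus a `period`
#'   column (index into `period_starts`, 1 before the second start).
#' @export
generate_scenario_series <- function(config, period_starts) {
  stopifnot(inherits(config, "generator_config"),
            !is.unsorted(period_starts, strictly = TRUE))
  met <- generate_met_series(config)
  year <- as.integer(format(met$date, "%Y"))
  period <- pmax(findInterval(year, period_starts), 1L)
  ta_new <- met$ta + config$warm_bias +
    (period - 1L) * config$warming_per_period
  # warming conserves the vapour pressure (specific humidity), so
  # relative humidity drops as the air warms
  vp <- vapour_pressure(met$ta, met$rh)
  met$ta <- ta_new
  met$rh <- clamp(100 * vp / saturation_vp(ta_new), 10, 100)
  met$period <- period
  met
}

#' Generate a daily death-count series over given stress grades
#'
#' Counts are Poisson with mean `trend(t) * season(t) * (1 +
#' grade_effects[grade(t)])`: a linear trend from `deaths_start` to
#' `deaths_end`, a cosine seasonal factor with maximum on Jan 15, and a
#' multiplicative heat effect per stress grade.
#'
#' @param grades Data frame with columns `date` and `grade` (or
#'   `analysis_grade`), covering every day of the configured span.
#' @param config A [generator_config()].
#' @return Data frame `date`, `deaths` (integer), `mu` (the Poisson mean,
#'   kept for verification).
#' @export
generate_mortality_series <- function(grades, config) {
  stopifnot(inherits(config, "generator_config"), is.data.frame(grades))
  gcol <- if ("grade" %in% names(grades)) "grade" else "analysis_grade"
  stopifnot(gcol %in% names(grades))
  dates <- config_dates(config)
  if (!all(dates %in% grades$date)) {
    stop("grades must cover every day from ", config$start_year,
         " to ", config$end_year)
  }
  grades <- grades[match(dates, grades$date), ]
  g <- as.character(grades[[gcol]])
  if (!all(g %in% names(config$grade_effects))) {
    stop("unknown grade label(s): ",
         paste(setdiff(g, names(config$grade_effects)), collapse = ", "))
  }
  with_stream_seed(config$seed, "mortality", {
    n <- length(dates)
    frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    trend <- config$deaths_start +
      frac * (config$deaths_end - config$deaths_start)
    doy <- doy365(dates)
    season <- 1 + config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
    mu <- trend * season * (1 + unname(config$grade_effects[g]))
    data.frame(date = dates, deaths = stats::rpois(n, mu), mu = mu)
  })
}
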
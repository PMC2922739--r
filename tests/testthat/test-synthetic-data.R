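# Synthetic weather, scenario and mortality generators.

test_that("generator configuration is validated", {
  expect_error(generator_config(start_year = 2000, end_year = 2000),
               "end_year")
  expect_error(generator_config(deaths_start = 0), "deaths")
  expect_error(generator_config(ar1_coef = 1), "ar1_coef")
  expect_error(generator_config(grade_effects = c(hot = 1)), "grades")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- generator_config(start_year = 1990, end_year = 1994, seed = 11)
  expect_identical(generate_met_series(cfg), generate_met_series(cfg))
  expect_identical(generate_scenario_series(cfg, 1992),
                   generate_scenario_series(cfg, 1992))
  met <- generate_met_series(cfg)
  grades <- data.frame(date = met$date,
                       grade = factor("acceptable",
                                      levels = heatmort:::grade_levels))
  expect_identical(generate_mortality_series(grades, cfg),
                   generate_mortality_series(grades, cfg))
  cfg2 <- generator_config(start_year = 1990, end_year = 1994, seed = 12)
  expect_false(identical(generate_met_series(cfg)$ta,
                         generate_met_series(cfg2)$ta))
})

test_that("degenerate noise settings reproduce the pure sinusoid", {
  cfg <- generator_config(start_year = 1990, end_year = 1993, seed = 3,
                          met_resid_sd = 0, ar1_coef = 0)
  met <- generate_met_series(cfg)
  doy <- heatmort:::doy365(met$date)
  expected <- cfg$met_mean_temp +
    cfg$met_annual_amplitude * cos(2 * pi * (doy - 201) / 365.25)
  expect_equal(met$ta, expected, tolerance = 1e-12)
})

test_that("temperature residuals have the configured lag-1 autocorrelation", {
  cfg <- generator_config(start_year = 1970, end_year = 1999, seed = 5)
  met <- generate_met_series(cfg)
  doy <- heatmort:::doy365(met$date)
  seasonal <- cfg$met_mean_temp +
    cfg$met_annual_amplitude * cos(2 * pi * (doy - 201) / 365.25)
  resid <- met$ta - seasonal
  acf1 <- stats::cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(acf1 - cfg$ar1_coef), 0.05)
})

test_that("met variables respect their physical bounds", {
  cfg <- generator_config(start_year = 1980, end_year = 1989, seed = 8)
  met <- generate_met_series(cfg)
  expect_true(all(met$rh >= 10 & met$rh <= 100))
  expect_true(all(met$wind >= 0))
  expect_true(all(met$cloud %in% 0:8))
  expect_equal(nrow(met), as.integer(as.Date("1990-01-01") -
                                       as.Date("1980-01-01")))
})

test_that("scenario series reduces to the met series at zero perturbation", {
  cfg <- generator_config(start_year = 1990, end_year = 1999, seed = 21,
                          warm_bias = 0, warming_per_period = 0)
  met <- generate_met_series(cfg)
  scen <- generate_scenario_series(cfg, period_starts = c(1990, 1994, 1998))
  expect_equal(scen$ta, met$ta)
  expect_equal(scen$rh, met$rh, tolerance = 1e-12)
  expect_identical(scen[c("wind", "cloud")], met[c("wind", "cloud")])
})

test_that("warm bias is exactly additive within the first period", {
  cfg0 <- generator_config(start_year = 1990, end_year = 1995, seed = 21,
                           warm_bias = 0, warming_per_period = 0)
  cfg2 <- generator_config(start_year = 1990, end_year = 1995, seed = 21,
                           warm_bias = 2, warming_per_period = 0)
  expect_equal(generate_scenario_series(cfg2, 1990)$ta,
               generate_scenario_series(cfg0, 1990)$ta + 2)
})

test_that("per-period warming accumulates across period starts", {
  cfg <- generator_config(start_year = 1971, end_year = 2060, seed = 33,
                          warm_bias = 0, warming_per_period = 1)
  scen <- generate_scenario_series(cfg, period_starts = c(1971, 2001, 2031))
  year <- as.integer(format(scen$date, "%Y"))
  m1 <- mean(scen$ta[year <= 2000])
  m3 <- mean(scen$ta[year >= 2031])
  # configured difference is exactly 2 degC plus sampling error of the
  # AR(1) residual means (se about 0.1 degC over 30 years)
  expect_lt(abs((m3 - m1) - 2), 0.5)
})

test_that("mortality is pure Poisson noise when all structure is off", {
  cfg <- generator_config(start_year = 1990, end_year = 1999, seed = 14,
                          deaths_start = 50, deaths_end = 50,
                          seasonal_amplitude = 0,
                          grade_effects = c(acceptable = 0, slight = 0,
                                            moderate = 0, strong = 0,
                                            extreme = 0))
  dates <- seq(as.Date("1990-01-01"), as.Date("1999-12-31"), by = "day")
  grades <- data.frame(date = dates,
                       grade = factor("acceptable",
                                      levels = heatmort:::grade_levels))
  mort <- generate_mortality_series(grades, cfg)
  expect_true(all(mort$mu == 50))
  se <- sqrt(50 / nrow(mort))
  expect_lt(abs(mean(mort$deaths) - 50), 3 * se)
  expect_true(all(mort$deaths >= 0 & mort$deaths == round(mort$deaths)))
})

test_that("grade effects scale mortality multiplicatively", {
  cfg <- generator_config(start_year = 1970, end_year = 1999, seed = 9,
                          grade_effects = c(acceptable = 0, slight = 0,
                                            moderate = 0, strong = 0,
                                            extreme = 0.13))
  dates <- seq(as.Date("1970-01-01"), as.Date("1999-12-31"), by = "day")
  # ~25 extreme days per July, >200 in total
  grade <- rep("acceptable", length(dates))
  july <- format(dates, "%m") == "07"
  grade[july & as.POSIXlt(dates)$mday <= 25] <- "extreme"
  grades <- data.frame(date = dates,
                       grade = factor(grade,
                                      levels = heatmort:::grade_levels))
  mort <- generate_mortality_series(grades, cfg)
  ex <- grade == "extreme"
  baseline_mu <- mort$mu[ex] / 1.13
  ratio <- mean(mort$deaths[ex]) / mean(baseline_mu)
  se <- sqrt(mean(mort$mu[ex]) / sum(ex)) / mean(baseline_mu)
  expect_lt(abs(ratio - 1.13), 4 * se)
})

test_that("seasonal mortality cycle peaks in winter at the set amplitude", {
  cfg <- generator_config(start_year = 1980, end_year = 1999, seed = 10,
                          deaths_start = 60, deaths_end = 60,
                          seasonal_amplitude = 0.2,
                          grade_effects = c(acceptable = 0, slight = 0,
                                            moderate = 0, strong = 0,
                                            extreme = 0))
  dates <- seq(as.Date("1980-01-01"), as.Date("1999-12-31"), by = "day")
  grades <- data.frame(date = dates,
                       grade = factor("acceptable",
                                      levels = heatmort:::grade_levels))
  mort <- generate_mortality_series(grades, cfg)
  mo <- format(dates, "%m")
  ratio <- mean(mort$mu[mo == "01"]) / mean(mort$mu[mo == "07"])
  expect_equal(ratio, 1.2 / 0.8, tolerance = 0.01)
  ratio_obs <- mean(mort$deaths[mo == "01"]) / mean(mort$deaths[mo == "07"])
  expect_lt(abs(ratio_obs - 1.5), 0.1)
})

test_that("missing grade days are rejected", {
  cfg <- generator_config(start_year = 1990, end_year = 1991, seed = 2)
  grades <- data.frame(date = as.Date("1990-01-01"),
                       grade = factor("acceptable",
                                      levels = heatmort:::grade_levels))
  expect_error(generate_mortality_series(grades, cfg), "every day")
})

test_that("zero injected effects yield grade means indistinguishable from 0", {
  # pipeline property: with no heat effect, per-grade 95% CIs cover 0 in
  # at least 90% of replicates (grades still assigned from real PET)
  fx <- station_fixture()
  zero_cfg <- generator_config(start_year = 1980, end_year = 1993,
                               seed = 0,
                               grade_effects = c(acceptable = 0, slight = 0,
                                                 moderate = 0, strong = 0,
                                                 extreme = 0))
  covered <- 0L
  total <- 0L
  for (seed in 1:10) {
    zero_cfg$seed <- seed
    mort <- generate_mortality_series(fx$grades, zero_cfg)
    base <- mortality_baseline(mort[c("date", "deaths")])
    m <- merge(base, fx$grades, by = "date")
    m <- m[analysis_window(m$date), ]
    gm <- grade_means(m$relative, m$analysis_grade)
    gm <- gm[gm$n_days > 30, ]
    covered <- covered + sum(gm$ci_low <= 0 & gm$ci_high >= 0)
    total <- total + nrow(gm)
  }
  expect_gte(covered / total, 0.9)
})

test_that("injected heat effects are recovered in rank order", {
  # absolute recovery is attenuated by baseline absorption; the ordering
  # and positivity of the heat-stress contrasts are the identifiable part
  fx <- station_fixture()
  mort <- fx$mort
  base <- mortality_baseline(mort[c("date", "deaths")])
  m <- merge(base, fx$grades, by = "date")
  m <- m[analysis_window(m$date), ]
  gm <- grade_means(m$relative, m$analysis_grade)
  means <- stats::setNames(gm$mean, gm$grade)
  expect_gt(means["extreme"], means["strong"])
  expect_gt(means["strong"], means["moderate"])
  expect_gt(means["extreme"] - means["acceptable"], 5)
})
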
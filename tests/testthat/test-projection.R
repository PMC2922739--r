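# Percentile bias correction, day counts, adaptation approaches and
# cumulated heat-related mortality.

cal_dates <- seq(as.Date("1971-01-01"), as.Date("2000-12-31"), by = "day")

synth_pet <- function(seed, bias = 0) {
  set.seed(seed)
  doy <- heatmort:::doy365(cal_dates)
  18 + 16 * cos(2 * pi * (doy - 201) / 365) + rnorm(length(cal_dates), 0, 5) +
    bias
}

test_that("quantile mapping is the identity for identical series", {
  pet <- synth_pet(1)
  cal <- calibrate_thresholds(pet, pet)
  # up to one order-statistic gap in the upper tail
  expect_equal(as.numeric(cal), c(29, 35, 41), tolerance = 0.005)
})

test_that("a constant +2 shift moves every threshold by +2", {
  pet <- synth_pet(2)
  cal <- calibrate_thresholds(pet, pet + 2)
  expect_equal(as.numeric(cal), c(31, 37, 43), tolerance = 0.005)
})

test_that("calibration equalises exceedance counts for a warm-biased model", {
  station <- synth_pet(3)
  model <- synth_pet(4, bias = 2)
  cal <- calibrate_thresholds(station, model)
  expect_true(all(cal >= c(29, 35, 41))) # warm bias raises thresholds
  n_years <- 30
  for (k in 1:3) {
    base <- c(29, 35, 41)[k]
    station_days <- sum(station >= base) / n_years
    model_days <- sum(model >= cal[k]) / n_years
    expect_lt(abs(station_days - model_days), 1)
  }
  expect_error(calibrate_thresholds(station[1:300], model), "5 years")
})

test_that("day counts per grade partition the analysis window", {
  fx <- station_fixture()
  counts <- count_days_per_grade(fx$pet, c(1981, 1990), herate = TRUE)
  expect_equal(nrow(counts$annual), 10)
  # Apr-Oct has 214 days in every year, leap or not
  expect_equal(unname(rowSums(counts$annual[, -1])), rep(214, 10))
  expect_true(all(counts$mean_days >= 0))
})

test_that("a constructed series with exactly 7 extreme days per year counts 7", {
  dates <- seq(as.Date("1981-01-01"), as.Date("1992-12-31"), by = "day")
  pet <- rep(20, length(dates))
  md <- format(dates, "%m-%d")
  pet[md >= "07-01" & md <= "07-07"] <- 45 # seven extreme days each July
  pet_df <- data.frame(date = dates, pet = pet)
  counts <- count_days_per_grade(pet_df, c(1982, 1991), herate = FALSE)
  expect_equal(unname(counts$mean_days["extreme"]), 7)
  expect_equal(unname(counts$mean_days["moderate"]), 0)
  cold <- count_days_per_grade(data.frame(date = dates, pet = 15),
                               c(1982, 1991), herate = FALSE)
  expect_equal(unname(cold$mean_days[c("moderate", "strong", "extreme")]),
               c(0, 0, 0))
})

test_that("partially covered years are dropped with a warning", {
  dates <- seq(as.Date("1985-01-01"), as.Date("1990-06-30"), by = "day")
  pet_df <- data.frame(date = dates, pet = 20)
  expect_warning(counts <- count_days_per_grade(pet_df, c(1985, 1990),
                                                herate = FALSE),
                 "not fully covered")
  expect_equal(nrow(counts$annual), 5)
})

test_that("relative change reproduces the worked percentage arithmetic", {
  expect_equal(round(relative_change(7, 16)), 129)
  expect_equal(round(relative_change(29, 37)), 28)
  expect_equal(relative_change(10, 10), 0)
  expect_warning(out <- relative_change(0, 5), "zero reference")
  expect_true(is.na(out))
})

test_that("projected sensitivity follows the two adaptation approaches", {
  year <- 1971:2006
  decl <- fit_trend(year, 8 - 0.096 * (year - 1971) + # -0.96 per decade
                      c(0.2, -0.2)[1 + (year %% 2)], policy = "either")
  expect_true(decl$significant && decl$slope < 0)
  expect_equal(project_sensitivity("no_adaptation", 5.8, decl, 80), 5.8)
  end_val <- end_of_period_sensitivity(decl)
  cons <- conservative_trend(decl)
  expect_equal(project_sensitivity("adaptation", 5.8, decl, 50),
               end_val + cons * 5, tolerance = 1e-9)
  # far horizons are floored at zero, never negative heat mortality
  expect_equal(project_sensitivity("adaptation", 5.8, decl, 5000), 0)
  # non-significant trend: end-of-period value held constant
  set.seed(2)
  flat <- fit_trend(year, rnorm(36, 13, 4))
  expect_false(flat$significant)
  for (h in c(0, 30, 90)) {
    expect_equal(project_sensitivity("adaptation", 13, flat, h),
                 end_of_period_sensitivity(flat))
  }
})

test_that("cumulated mortality is the days-by-sensitivity product", {
  expect_equal(cumulated_mortality(0, 13), 0)
  expect_equal(cumulated_mortality(7, 13), 91)
  expect_error(cumulated_mortality(-1, 5), "days_per_year")
})

test_that("with constant sensitivity the cumulated change equals the day change", {
  set.seed(8)
  for (i in 1:20) {
    ref_days <- runif(1, 1, 40)
    fut_days <- runif(1, 0, 80)
    sens <- runif(1, 0.5, 15)
    expect_equal(relative_change(cumulated_mortality(ref_days, sens),
                                 cumulated_mortality(fut_days, sens)),
                 relative_change(ref_days, fut_days), tolerance = 1e-12)
  }
})

test_that("adaptation never projects more cumulated mortality than none", {
  year <- 1971:2006
  decl <- fit_trend(year, 8 - 0.096 * (year - 1971) +
                      c(0.2, -0.2)[1 + (year %% 2)], policy = "either")
  mean_sens <- 5.8
  for (h in c(0, 20, 60, 120)) {
    days <- 30
    s_no <- project_sensitivity("no_adaptation", mean_sens, decl, h)
    s_ad <- project_sensitivity("adaptation", mean_sens, decl, h)
    expect_lte(cumulated_mortality(days, s_ad),
               cumulated_mortality(days, s_no))
  }
})

test_that("change significance has power for a clear day-count shift", {
  set.seed(17)
  detected <- 0L
  for (i in 1:40) {
    ref <- rnorm(30, 7, 2)
    fut <- rnorm(30, 11, 2)
    detected <- detected + (change_significance(ref, fut)$p < 0.01)
  }
  expect_gte(detected / 40, 0.95)
  same <- change_significance(rep(5, 12), rep(5, 12))
  expect_equal(same$p, 1)
  expect_error(change_significance(1:5, 1:20), "10 annual")
})

test_that("the full projection obeys its cross-cutting identities", {
  fx <- station_fixture()
  # scenario built on the same climate with a warm bias and warming
  cfg_s <- generator_config(start_year = 1980, end_year = 2007, seed = 421,
                            warm_bias = 1.5, warming_per_period = 1)
  scen <- generate_scenario_series(cfg_s, period_starts = c(1994, 2001))
  pet_m <- pet_series(scen)
  mort <- fx$mort
  res <- run_pipeline(fx$met, mort[c("date", "deaths")])
  periods <- list(ref = c(1981, 1992), fut = c(1996, 2007))
  proj <- project_mortality(fx$pet, pet_m, res$sensitivity, res$trends,
                            periods = periods, exam_end = 1993)
  expect_s3_class(proj, "projection_result")
  # no-adaptation identity: cumulated change == day-count change
  na_rows <- proj[proj$approach == "no_adaptation" & !is.na(proj$cumulated), ]
  expect_equal(na_rows$change_cumulated, na_rows$change_days,
               tolerance = 1e-9)
  # reference period against itself: zero change, p = 1
  ref_rows <- proj[proj$period == "1981-1992", ]
  expect_true(all(abs(ref_rows$change_days) < 1e-9))
  expect_true(all(ref_rows$p_change > 0.999))
  # calibrated thresholds exceed the base ones for a warm-biased model
  expect_true(all(attr(proj, "thresholds") >= c(29, 35, 41)))
})
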
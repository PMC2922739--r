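# Climate-scenario projection: percentile bias correction of the model
# PET thresholds against the station distribution, day counts per stress
# grade and period, projected sensitivity with and without long-term
# adaptation, and cumulated heat-related mortality (percent-days: 100
# corresponds to the death cases of a single day without heat stress).

default_periods <- list(reference = c(1971, 2000),
                        p2011 = c(2011, 2040),
                        p2041 = c(2041, 2070),
                        p2071 = c(2071, 2100))

#' Percentile bias correction of stress thresholds for a model series
#'
#' Climate models tend to overestimate high PET. For each base threshold
#' the empirical non-exceedance percentile in the station calibration
#' series is computed, and the threshold is replaced by the model
#' series' quantile at that percentile, so station and model have the
#' same number of days above the (corrected) threshold during the
#' calibration period. Quantiles use the median-unbiased estimator
#' (type 8).
#'
#' @param station_pet Station PET over the calibration period and
#'   analysis window, degC.
#' @param model_pet Model PET over the same period and window, degC.
#' @param thresholds Base thresholds, degC (default moderate/strong/
#'   extreme bounds 29, 35, 41).
#' @param min_years Minimum calibration length in years, counted as 214
#'   window days each (default 5).
#' @return Named numeric vector of calibrated thresholds with the
#'   station percentiles as attribute `"percentiles"`.
#' @export
calibrate_thresholds <- function(station_pet, model_pet,
                                 thresholds = base_thresholds()[-1],
                                 min_years = 5) {
  station_pet <- station_pet[!is.na(station_pet)]
  model_pet <- model_pet[!is.na(model_pet)]
  if (length(station_pet) < min_years * 214 ||
      length(model_pet) < min_years * 214) {
    stop("calibration series must cover at least ", min_years, " years")
  }
  p <- vapply(thresholds, function(t) mean(station_pet <= t), numeric(1))
  out <- stats::quantile(model_pet, p, type = 8, names = FALSE)
  if (is.unsorted(out)) stop("calibrated thresholds are not increasing")
  names(out) <- names(thresholds)
  attr(out, "percentiles") <- p
  out
}

#' Days per year in each analysis grade over a period
#'
#' Counts Apr-Oct days per year falling in each of the four analysis
#' grades (acceptable incl. slight, moderate, strong, extreme), using
#' either fixed or HeRATE-adapted thresholds. Years not fully covered by
#' the series are dropped with a warning.
#'
#' @param pet_df Data frame `date`, `pet` (daily, consecutive).
#' @param period Length-2 numeric, first and last calendar year.
#' @param thresholds Lower bounds of moderate, strong and extreme heat
#'   stress, degC (length 3; e.g. calibrated ones). The comfort bound is
#'   not needed for the four analysis grades.
#' @param herate Apply the adaptive shift (default `TRUE`); the
#'   climatology is computed from the full `pet_df`, i.e. the series'
#'   own climate.
#' @param window_start,window_end Analysis window as `"mm-dd"` (default
#'   Apr 1 - Oct 31).
#' @param ... Passed to [adapted_shift()].
#' @return List of class `period_day_counts`: `period`, `annual` (data
#'   frame year x grade counts), `mean_days` (named vector, days/year).
#' @export
count_days_per_grade <- function(pet_df, period,
                                 thresholds = base_thresholds()[-1],
                                 herate = TRUE,
                                 window_start = "04-01",
                                 window_end = "10-31", ...) {
  stopifnot(all(c("date", "pet") %in% names(pet_df)), length(thresholds) == 3L)
  shift <- if (herate) {
    adapted_shift(pet_df$pet, pet_df$date, ...)
  } else {
    rep(0, nrow(pet_df))
  }
  idx <- 1L + (pet_df$pet >= thresholds[1] + shift) +
    (pet_df$pet >= thresholds[2] + shift) +
    (pet_df$pet >= thresholds[3] + shift)
  grade <- factor(analysis_grade_levels[idx], levels = analysis_grade_levels)

  year <- as.integer(format(pet_df$date, "%Y"))
  in_window <- analysis_window(pet_df$date, window_start, window_end)
  keep <- in_window & year >= period[1] & year <= period[2]

  window_len <- vapply(period[1]:period[2], function(y) {
    sum(analysis_window(seq(as.Date(sprintf("%d-01-01", y)),
                            as.Date(sprintf("%d-12-31", y)), by = "day"),
                        window_start, window_end))
  }, numeric(1))
  have <- table(factor(year[keep], levels = period[1]:period[2]))
  full <- as.numeric(have) == window_len
  if (!all(full)) {
    warning("dropping ", sum(!full), " year(s) not fully covered")
  }
  years <- (period[1]:period[2])[full]
  keep <- keep & year %in% years
  tab <- table(year = year[keep], grade = grade[keep])
  annual <- as.data.frame.matrix(tab)
  annual <- cbind(year = as.integer(rownames(annual)), annual)
  rownames(annual) <- NULL
  mean_days <- colMeans(annual[analysis_grade_levels])
  structure(list(period = period, annual = annual, mean_days = mean_days),
            class = "period_day_counts")
}

#' Relative change of a future value against a reference
#'
#' @param reference Reference value (> 0).
#' @param future Future value.
#' @return `100 * (future - reference) / reference`, %; `NA` with a
#'   warning if the reference is zero.
#' @examples
#' round(relative_change(7, 16)) # 129
#' @export
relative_change <- function(reference, future) {
  out <- ifelse(reference > 0, 100 * (future - reference) / reference,
                NA_real_)
  if (anyNA(out)) warning("relative change undefined for zero reference")
  out
}

#' Projected sensitivity of a grade under the two adaptation approaches
#'
#' Without adaptation the mean sensitivity of the period of examination
#' is applied unchanged at any horizon. With adaptation, a significant
#' declining trend is extrapolated at the statistically conservative
#' rate from the end-of-period value, floored at 0%; a non-significant
#' trend keeps the end-of-period value constant.
#'
#' @param approach `"no_adaptation"` or `"adaptation"`.
#' @param mean_sensitivity Period-of-examination mean relative mortality
#'   of the grade, %.
#' @param trend `trend_estimate` for the grade from [fit_trend()].
#' @param horizon Years past the end of the period of examination
#'   (>= 0).
#' @return Sensitivity, %.
#' @export
project_sensitivity <- function(approach = c("no_adaptation", "adaptation"),
                                mean_sensitivity, trend, horizon) {
  approach <- match.arg(approach)
  stopifnot(horizon >= 0)
  if (approach == "no_adaptation") return(mean_sensitivity)
  if (isTRUE(trend$significant) && trend$slope < 0) {
    base <- end_of_period_sensitivity(trend)
    pmax(base + conservative_trend(trend) * horizon / 10, 0)
  } else {
    end_of_period_sensitivity(trend)
  }
}

#' Cumulated heat-related mortality
#'
#' Product of mean days per year in a grade and the grade's sensitivity,
#' in percent-days per year; 100 corresponds to the death cases of one
#' day without heat stress.
#'
#' @param days_per_year Mean days/year in the grade.
#' @param sensitivity Mean relative mortality on such days, %.
#' @return Percent-days per year.
#' @examples
#' cumulated_mortality(7, 13) # 91
#' @export
cumulated_mortality <- function(days_per_year, sensitivity) {
  stopifnot(all(days_per_year >= 0))
  days_per_year * sensitivity
}

#' Significance of a change in annual day counts between two periods
#'
#' Welch t-test on the annual values (day counts or annual cumulated
#' mortality) of the reference and a future period.
#'
#' @param reference,future Annual values, one per year (>= 10 each).
#' @return List `t`, `p`, `df`.
#' @export
change_significance <- function(reference, future) {
  if (length(reference) < 10 || length(future) < 10) {
    stop("need at least 10 annual values per period")
  }
  res <- compare_groups(future, reference)
  list(t = res$t, p = res$p, df = res$df)
}

#' Project cumulated heat-related mortality over the scenario periods
#'
#' End-to-end projection for one model/scenario series: calibrates the
#' thresholds on the reference period, counts days per grade and period,
#' applies both adaptation approaches to the heat-stress grades, and
#' reports cumulated mortality with relative changes against the
#' reference period. Grades whose projected sensitivity is not positive
#' are dropped from cumulated totals.
#'
#' @param station_pet Data frame `date`, `pet` of the station series
#'   (used for threshold calibration over the reference period).
#' @param model_pet Data frame `date`, `pet` of the scenario series
#'   covering reference and future periods.
#' @param sensitivities Data frame from [grade_means()] on the period of
#'   examination (four analysis grades).
#' @param trends Named list of `trend_estimate`s for the heat-stress
#'   grades (`moderate`, `strong`, `extreme`).
#' @param periods List of length-2 year vectors; first entry is the
#'   reference period (default 1971-2000, then 2011-2040, 2041-2070,
#'   2071-2100).
#' @param exam_end Final year of the period of examination (default
#'   2007); horizons are measured from it to each period midpoint.
#' @param herate Apply short-term adaptation when counting days.
#' @param ... Passed to [count_days_per_grade()].
#' @return Data frame of class `projection_result`: one row per period,
#'   approach and heat-stress grade with days/year, sensitivity used,
#'   cumulated mortality, relative changes vs. the reference period and
#'   the p-value of the day-count change.
#' @export
project_mortality <- function(station_pet, model_pet, sensitivities, trends,
                              periods = default_periods, exam_end = 2007,
                              herate = TRUE, ...) {
  ref_period <- periods[[1]]
  ref_years <- function(df) {
    y <- as.integer(format(df$date, "%Y"))
    df[y >= ref_period[1] & y <= ref_period[2] &
         analysis_window(df$date), ]
  }
  cal <- calibrate_thresholds(ref_years(station_pet)$pet,
                              ref_years(model_pet)$pet)
  counts <- lapply(periods, function(p) {
    count_days_per_grade(model_pet, p, thresholds = cal,
                         herate = herate, ...)
  })
  ref_counts <- counts[[1]]
  heat <- c("moderate", "strong", "extreme")
  rows <- list()
  for (pi in seq_along(periods)) {
    per <- periods[[pi]]
    horizon <- max(mean(per) - exam_end, 0)
    for (approach in c("no_adaptation", "adaptation")) {
      for (g in heat) {
        sens_row <- sensitivities[sensitivities$grade == g, ]
        sens <- project_sensitivity(approach, sens_row$mean,
                                    trends[[g]], horizon)
        ref_sens_ref <- if (approach == "no_adaptation") {
          sens_row$mean
        } else {
          project_sensitivity("adaptation", sens_row$mean, trends[[g]],
                              max(mean(ref_period) - exam_end, 0))
        }
        days <- unname(counts[[pi]]$mean_days[g])
        ref_days <- unname(ref_counts$mean_days[g])
        cum <- if (sens > 0) cumulated_mortality(days, sens) else NA_real_
        ref_cum <- if (ref_sens_ref > 0) {
          cumulated_mortality(ref_days, ref_sens_ref)
        } else {
          NA_real_
        }
        sig <- change_significance(ref_counts$annual[[g]],
                                   counts[[pi]]$annual[[g]])
        rows[[length(rows) + 1]] <- data.frame(
          period = paste(per, collapse = "-"), approach = approach,
          grade = g, days_per_year = days, sensitivity = sens,
          cumulated = cum,
          change_days = relative_change(ref_days, days),
          change_cumulated = if (!is.na(cum) && !is.na(ref_cum)) {
            relative_change(ref_cum, cum)
          } else {
            NA_real_
          },
          p_change = sig$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- cal
  class(out) <- c("projection_result", class(out))
  out
}
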
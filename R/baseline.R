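# Expected-mortality baseline: a wide Gaussian filter extracts the
# long-term level of the daily death counts, a multiplicative calendar-day
# factor restores the seasonal cycle, and daily deviations from the
# product are expressed in percent ("relative mortality").

#' Long-term trend of a daily count series by wide Gaussian smoothing
#'
#' Gaussian-weighted moving average with a one-year window (kernel
#' truncated at +/-182 days). The kernel scale is wide relative to the
#' window, so the filter behaves like a tapered 365-day boxcar: the annual
#' harmonic is attenuated to about 5% of its amplitude and the result
#' carries the long-term trend and level only. The seasonal cycle is put
#' back by [seasonal_expectation()].
#'
#' @param observed Daily counts, one value per consecutive day, no gaps.
#' @param sigma Kernel standard deviation in days (default 250; values
#'   near the spread of the window make the filter effectively uniform,
#'   small values let the annual cycle leak into the trend).
#' @param half_width Kernel truncation in days (default 182).
#' @return Numeric vector of the same length; `NA` within `half_width`
#'   days of either end (no extrapolation).
#' @examples
#' x <- rep(50, 365 * 4)
#' trend <- smooth_longterm(x)
#' range(trend, na.rm = TRUE) # 50 50
#' @export
smooth_longterm <- function(observed, sigma = 250, half_width = 182L) {
  n <- length(observed)
  if (n < 3 * 365) stop("need at least 3 full years of daily counts")
  if (anyNA(observed)) stop("observed series must not contain missing days")
  k <- stats::dnorm(-half_width:half_width, 0, sigma)
  k <- k / sum(k)
  as.numeric(stats::filter(observed, k, sides = 2))
}

#' Expected mortality: trend times smoothed seasonal factor
#'
#' The seasonal factor is the calendar-day mean of `observed / trend`
#' (leap days share the Feb 28 bin), circularly smoothed with a 15-day
#' Gaussian window (sigma 5 days) and renormalised to mean one over the
#' calendar year, so the expectation preserves the smoothed level.
#'
#' @param observed Daily counts.
#' @param trend Output of [smooth_longterm()] for the same days.
#' @param dates Dates of the series (class `Date`), same length.
#' @return List with `expected` (daily series, `NA` where the trend is
#'   undefined) and `seasonal` (the length-365 factor).
#' @export
seasonal_expectation <- function(observed, trend, dates) {
  stopifnot(length(observed) == length(trend),
            length(observed) == length(dates))
  if (any(trend <= 0, na.rm = TRUE)) stop("trend must be positive")
  doy <- doy365(dates)
  ratio <- observed / trend
  s_raw <- vapply(1:365, function(d) {
    mean(ratio[doy == d], na.rm = TRUE)
  }, numeric(1))
  if (anyNA(s_raw)) stop("every calendar day needs at least one interior value")
  s <- circular_smooth(s_raw, window = 15L, sigma = 5)
  s <- s / mean(s)
  list(expected = trend * s[doy], seasonal = s)
}

#' Relative mortality: percent deviation from the expected baseline
#'
#' @param observed Daily counts.
#' @param expected Expected mortality for the same days (positive where
#'   defined).
#' @return `100 * (observed - expected) / expected`, `NA` where the
#'   expectation is undefined.
#' @examples
#' relative_mortality(55, 50) # +10
#' @export
relative_mortality <- function(observed, expected) {
  if (any(expected <= 0, na.rm = TRUE)) stop("expected mortality must be > 0")
  100 * (observed - expected) / expected
}

#' Full baseline computation for a mortality series
#'
#' Convenience wrapper: trend, seasonal expectation and relative
#' mortality in one call.
#'
#' @param mortality Data frame with columns `date` and `deaths` (daily,
#'   consecutive, no gaps), as from [generate_mortality_series()] or
#'   [read_mortality_csv()].
#' @param sigma,half_width Passed to [smooth_longterm()].
#' @return The input data frame with columns `expected` and `relative`
#'   added (both `NA` within `half_width` days of either end).
#' @export
mortality_baseline <- function(mortality, sigma = 250, half_width = 182L) {
  stopifnot(all(c("date", "deaths") %in% names(mortality)))
  if (any(diff(as.integer(mortality$date)) != 1L)) {
    stop("mortality series must cover consecutive days without gaps")
  }
  trend <- smooth_longterm(mortality$deaths, sigma, half_width)
  exp_fit <- seasonal_expectation(mortality$deaths, trend, mortality$date)
  mortality$expected <- exp_fit$expected
  mortality$relative <- ifelse(is.na(exp_fit$expected), NA_real_,
                               relative_mortality(mortality$deaths,
                                                  exp_fit$expected))
  attr(mortality, "seasonal") <- exp_fit$seasonal
  mortality
}
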
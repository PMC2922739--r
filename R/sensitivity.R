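# Mortality sensitivity per stress grade: mean relative mortality with
# confidence intervals, group contrasts, decadal trends of the annual
# means (OLS slope + nonparametric Mann-Kendall), and the two rules used
# to carry sensitivity into the future: the statistically conservative
# trend (CI bound with the least decline) for significant declining
# trends, and the fitted value at the final analysis year otherwise.

#' Mean relative mortality per stress grade
#'
#' Arithmetic mean of daily relative mortality per grade with a normal
#' approximation confidence interval (`mean +/- z * se`); daily
#' autocorrelation is ignored.
#'
#' @param relative Daily relative mortality, % (NA allowed; dropped).
#' @param grade Matching factor of stress grades.
#' @param conf Confidence level (default 0.95).
#' @return Data frame `grade`, `mean`, `ci_low`, `ci_high`, `n_days`.
#'   Empty grades are reported with `n_days = 0` and `NA` statistics.
#' @export
grade_means <- function(relative, grade, conf = 0.95) {
  stopifnot(length(relative) == length(grade), is.factor(grade))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(levels(grade), function(g) {
    x <- relative[grade == g & !is.na(relative) & !is.na(grade)]
    n <- length(x)
    if (n == 0) {
      return(data.frame(grade = g, mean = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_days = 0L))
    }
    m <- mean(x)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
    data.frame(grade = g, mean = m, ci_low = m - z * se,
               ci_high = m + z * se, n_days = n)
  })
  do.call(rbind, out)
}

#' Compare mean relative mortality between two groups
#'
#' Welch two-sample t-test on daily relative mortality, e.g. women vs.
#' men within a stress grade.
#'
#' @param a,b Numeric vectors of daily relative mortality (NA dropped).
#' @return List `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least two observations")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                df = NA_real_, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Decadal trend of annual grade means
#'
#' Ordinary least squares of the annual mean relative mortality on the
#' calendar year; the slope is reported per 10 years with its confidence
#' interval and two-sided t-test p-value, together with the Mann-Kendall
#' test of the same series. `significant` applies the declared policy:
#' both tests below `alpha` (`policy = "both"`, default) or either one.
#'
#' @param year Calendar years (>= 10 distinct values for a stable fit; a
#'   shorter series is fitted with a warning).
#' @param annual_mean Annual mean relative mortality, %.
#' @param conf Confidence level for the slope CI (default 0.95).
#' @param alpha Significance level (default 0.05).
#' @param policy `"both"` or `"either"`.
#' @return List of class `trend_estimate`: `slope` (% per 10 years),
#'   `ci` (length 2, increasing), `p_regression`, `p_mann_kendall`,
#'   `significant`, `fit` (the `lm` object), `years`.
#' @export
fit_trend <- function(year, annual_mean, conf = 0.95, alpha = 0.05,
                      policy = c("both", "either")) {
  policy <- match.arg(policy)
  stopifnot(length(year) == length(annual_mean))
  ok <- !is.na(annual_mean)
  year <- year[ok]; annual_mean <- annual_mean[ok]
  if (length(year) < 4) stop("need at least 4 annual values")
  if (length(year) < 10) warning("fewer than 10 annual values; wide CI")
  fit <- stats::lm(annual_mean ~ year)
  # exact (zero-residual) fits are legitimate degenerate inputs here;
  # summary.lm's "essentially perfect fit" warning is handled explicitly
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)["year"]) * 10
  ci <- sort(unname(suppressWarnings(
    stats::confint(fit, "year", level = conf))) * 10)
  p_reg <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients["year", 4])) {
    1 # degenerate (e.g. constant) series: no evidence of trend
  } else {
    sm$coefficients["year", 4]
  }
  mk <- mann_kendall(annual_mean)
  sig <- if (policy == "both") {
    p_reg < alpha && mk$p < alpha
  } else {
    p_reg < alpha || mk$p < alpha
  }
  structure(list(slope = slope, ci = ci, p_regression = p_reg,
                 p_mann_kendall = mk$p, s = mk$s, significant = sig,
                 fit = fit, years = year),
            class = "trend_estimate")
}

#' Mann-Kendall trend test
#'
#' `S` is the sum of `sign(x_j - x_i)` over all pairs `i < j`; the
#' p-value uses the normal approximation with tie correction of the
#' variance and a continuity correction.
#'
#' @param x Numeric series (>= 4 values).
#' @return List `s`, `var_s`, `z`, `p` (two-sided).
#' @examples
#' mann_kendall(1:5)$s # 10
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  }
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
    sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (s == 0 || var_s == 0) {
    return(list(s = s, var_s = var_s, z = 0, p = 1))
  }
  z <- (s - sign(s)) / sqrt(var_s)
  list(s = s, var_s = var_s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Statistically conservative extrapolation trend
#'
#' For a significant declining trend, the slope carried into the future
#' is the confidence bound with the smallest absolute decline (the bound
#' nearest zero), not the point estimate.
#'
#' @param trend A `trend_estimate` from [fit_trend()] with
#'   `significant = TRUE` and negative slope.
#' @return Slope, % per 10 years.
#' @examples
#' tr <- structure(list(slope = -0.96, ci = c(-1.16, -0.77),
#'                      significant = TRUE), class = "trend_estimate")
#' conservative_trend(tr) # -0.77
#' @export
conservative_trend <- function(trend) {
  stopifnot(inherits(trend, "trend_estimate"))
  if (!isTRUE(trend$significant)) {
    stop("conservative_trend() requires a significant trend; ",
         "use end_of_period_sensitivity() otherwise")
  }
  if (trend$slope >= 0) stop("conservative_trend() requires a declining trend")
  max(trend$ci)
}

#' Sensitivity at the end of the period of examination
#'
#' For grades without a significant trend, the sensitivity carried into
#' the future is the fitted regression line evaluated at the final
#' analysis year (robust to single-year noise), held constant thereafter.
#'
#' @param trend A `trend_estimate` from [fit_trend()].
#' @param final_year Year at which to evaluate (default: last fitted
#'   year).
#' @return Sensitivity, %.
#' @export
end_of_period_sensitivity <- function(trend, final_year = NULL) {
  stopifnot(inherits(trend, "trend_estimate"))
  final_year <- final_year %||% max(trend$years)
  unname(stats::predict(trend$fit, data.frame(year = final_year)))
}

#' Annual mean relative mortality per grade
#'
#' Helper aggregating daily relative mortality to one mean per year and
#' grade, the input of [fit_trend()].
#'
#' @param relative Daily relative mortality, %.
#' @param grade Matching grade factor.
#' @param dates Matching dates.
#' @return Data frame `year`, `grade`, `mean`, `n_days`.
#' @export
annual_grade_means <- function(relative, grade, dates) {
  year <- as.integer(format(dates, "%Y"))
  ok <- !is.na(relative) & !is.na(grade)
  df <- data.frame(year = year[ok], grade = grade[ok], rel = relative[ok])
  agg <- stats::aggregate(rel ~ year + grade, df, mean)
  cnt <- stats::aggregate(rel ~ year + grade, df, length)
  names(agg)[3] <- "mean"
  agg$n_days <- cnt$rel
  agg[order(agg$grade, agg$year), ]
}
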
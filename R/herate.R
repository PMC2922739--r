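# Adaptive thermo-physiological stress grading. The upper comfort limit
# of PET (23 degC) and the heat-stress thresholds above it (23/29/35/41,
# slight/moderate/strong/extreme) are shifted day by day according to the
# thermal conditions of the previous 30 days, representing short-term
# acclimatisation; a warm previous month raises the limits, a cold one
# lowers them.

grade_levels <- c("acceptable", "slight", "moderate", "strong", "extreme")

analysis_grade_levels <- c("acceptable", "moderate", "strong", "extreme")

#' Base PET thresholds of the heat-stress grades
#'
#' Lower bounds of slight, moderate, strong and extreme heat stress in
#' degC; PET below the first value is thermally acceptable.
#'
#' @return Named numeric vector `c(slight = 23, moderate = 29,
#'   strong = 35, extreme = 41)`.
#' @export
base_thresholds <- function() {
  c(slight = 23, moderate = 29, strong = 35, extreme = 41)
}

#' Calendar-day PET climatology
#'
#' Mean PET per calendar day over the full input period (leap days share
#' the Feb 28 bin), circularly smoothed with a 15-day Gaussian window
#' (sigma 5 days). Serves as the reference from which the 30-day thermal
#' anomaly of the adaptive shift is measured; for climate-scenario series
#' it is recomputed from that series, so short-term acclimatisation is
#' always relative to the series' own climate.
#'
#' @param pet Daily PET, degC.
#' @param dates Matching dates.
#' @return Length-365 numeric vector.
#' @export
pet_climatology <- function(pet, dates) {
  doy <- doy365(dates)
  clim <- vapply(1:365, function(d) mean(pet[doy == d], na.rm = TRUE),
                 numeric(1))
  if (anyNA(clim)) stop("PET series must cover every calendar day at least once")
  circular_smooth(clim, window = 15L, sigma = 5)
}

#' Adaptive threshold shift from the previous 30 days of PET
#'
#' The shift is a fraction `w` of the exponentially weighted mean PET
#' anomaly (relative to the calendar-day climatology) over the preceding
#' `window` days, with weight half-life `half_life` days, clamped to
#' `+/- clamp` degC. With `w = 0` the shift is identically zero and
#' grading reduces to the fixed thresholds.
#'
#' @param pet Daily PET, degC (consecutive days).
#' @param dates Matching dates.
#' @param w Fraction of the anomaly applied (default 0.5).
#' @param half_life Weight half-life, days (default 10).
#' @param window Look-back length, days (default 30); the current day is
#'   excluded.
#' @param clamp Maximum absolute shift, degC (default 6).
#' @param climatology Optional length-365 calendar-day reference (defaults
#'   to [pet_climatology()] of the input itself).
#' @return Numeric vector of shifts, degC; the first `window` days have
#'   shift 0 and are flagged in the `"cold_start"` attribute.
#' @export
adapted_shift <- function(pet, dates, w = 0.5, half_life = 10, window = 30L,
                          clamp = 6, climatology = NULL) {
  n <- length(pet)
  stopifnot(length(dates) == n)
  if (is.null(climatology)) climatology <- pet_climatology(pet, dates)
  if (w == 0) {
    shift <- rep(0, n)
    attr(shift, "cold_start") <- seq_len(min(window, n))
    return(shift)
  }
  lambda <- 2^(-1 / half_life)
  wts <- lambda^(seq_len(window) - 1) # lag 1 .. window
  wts <- wts / sum(wts)
  # exponentially weighted mean PET over the preceding `window` days;
  # comparing it to *today's* climatology makes thresholds lag the
  # seasonal ramp, so early-summer heat is graded more severely
  ewm <- rep(NA_real_, n)
  if (n > window) {
    lagged <- vapply(seq_len(window), function(k) {
      pet[seq.int(window + 1 - k, n - k)]
    }, numeric(n - window))
    ewm[(window + 1):n] <- as.numeric(lagged %*% wts)
  }
  shift <- clamp(w * (ewm - climatology[doy365(dates)]), -clamp, clamp)
  shift[is.na(shift)] <- 0
  attr(shift, "cold_start") <- seq_len(min(window, n))
  shift
}

#' Assign a thermo-physiological stress grade to each day
#'
#' Half-open, lower-closed intervals between the (shifted) thresholds:
#' a PET exactly on a threshold belongs to the higher grade.
#'
#' @param pet Daily PET, degC.
#' @param shift Per-day threshold shift, degC (default 0; recycled).
#' @param thresholds Base thresholds as from [base_thresholds()].
#' @return Factor with levels acceptable, slight, moderate, strong,
#'   extreme.
#' @examples
#' assign_grade(c(22, 30, 44)) # acceptable moderate extreme
#' @export
assign_grade <- function(pet, shift = 0, thresholds = base_thresholds()) {
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds, strictly = TRUE))
  shift <- rep_len(shift, length(pet))
  idx <- 1L + (pet >= thresholds[1] + shift) + (pet >= thresholds[2] + shift) +
    (pet >= thresholds[3] + shift) + (pet >= thresholds[4] + shift)
  factor(grade_levels[idx], levels = grade_levels)
}

#' Collapse grading to the four analysis grades
#'
#' The climate-impact analysis uses three heat-stress grades (moderate to
#' extreme) and one large grade of thermal acceptability; slight heat
#' stress is folded into "acceptable".
#'
#' @param grade Factor from [assign_grade()].
#' @return Factor with levels acceptable, moderate, strong, extreme.
#' @export
collapse_grades <- function(grade) {
  g <- as.character(grade)
  g[g == "slight"] <- "acceptable"
  factor(g, levels = analysis_grade_levels)
}

#' Grade a daily PET series with or without short-term adaptation
#'
#' @param pet_df Data frame with columns `date` and `pet`.
#' @param herate Apply the adaptive shift (default `TRUE`); `FALSE` grades
#'   against the fixed base thresholds.
#' @param thresholds Base thresholds.
#' @param ... Passed to [adapted_shift()].
#' @return Data frame `date`, `pet`, `shift`, `grade` (five levels),
#'   `analysis_grade` (four levels).
#' @export
grade_series <- function(pet_df, herate = TRUE,
                         thresholds = base_thresholds(), ...) {
  stopifnot(all(c("date", "pet") %in% names(pet_df)))
  shift <- if (herate) {
    adapted_shift(pet_df$pet, pet_df$date, ...)
  } else {
    rep(0, nrow(pet_df))
  }
  grade <- assign_grade(pet_df$pet, shift, thresholds)
  data.frame(date = pet_df$date, pet = pet_df$pet,
             shift = as.numeric(shift), grade = grade,
             analysis_grade = collapse_grades(grade))
}
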
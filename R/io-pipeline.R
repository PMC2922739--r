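# File formats, the April-October analysis window and the end-to-end
# pipeline. CSVs use ISO-8601 dates and plain headers; times are local
# (the reference hour is a fixed local hour, no timezone arithmetic).

#' April-October analysis-window filter
#'
#' The heat analysis uses only the warm season of each year. The window
#' is implemented literally as Apr 1 - Oct 31 (214 days in a non-leap
#' year) even though it is conventionally spoken of as "six months".
#'
#' @param dates Dates.
#' @param start,end Window bounds as `"mm-dd"` strings, inclusive.
#' @return Logical vector.
#' @examples
#' sum(analysis_window(seq(as.Date("2001-01-01"),
#'                         as.Date("2001-12-31"), by = "day"))) # 214
#' @export
analysis_window <- function(dates, start = "04-01", end = "10-31") {
  md <- format(dates, "%m-%d")
  if (start > end) stop("window start must precede end within the year")
  md >= start & md <= end
}

#' Read a daily meteorological CSV
#'
#' Required columns: `date` (ISO-8601), `ta`, `rh`, `wind`, `cloud`;
#' optional `vp` (used instead of `rh` if present) and `pet`
#' (precomputed PET, bypassing the energy-balance engine downstream).
#' Dates must be strictly increasing; physical bounds are enforced.
#'
#' @param path CSV path.
#' @return Validated data frame with a `Date` column `date`.
#' @export
read_met_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty met file: ", path)
  need <- c("date", "ta")
  if (!all(need %in% names(df))) {
    stop("met file must have columns ", paste(need, collapse = ", "))
  }
  if (!("rh" %in% names(df) || "vp" %in% names(df) || "pet" %in% names(df))) {
    stop("met file needs an rh or vp column (or precomputed pet)")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stop("unparseable date at row ", which(is.na(df$date))[1])
  }
  if (any(diff(as.integer(df$date)) <= 0)) {
    stop("duplicate or non-monotone dates at row ",
         which(diff(as.integer(df$date)) <= 0)[1] + 1)
  }
  check_bound <- function(col, lo, hi) {
    if (!col %in% names(df)) return(invisible())
    bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
    if (length(bad)) {
      stop(col, " out of [", lo, ", ", hi, "] at row ", bad[1])
    }
  }
  check_bound("rh", 0, 100)
  check_bound("wind", 0, Inf)
  check_bound("cloud", 0, 8)
  df
}

#' Read a daily mortality CSV
#'
#' Required columns: `date` (ISO-8601), `deaths`; optional strata such as
#' `deaths_f`, `deaths_m`, `deaths_cr`. Counts must be non-negative
#' integers; if both sex columns are present their sum must equal the
#' total. Gaps in the date sequence are reported as a warning.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty mortality file: ", path)
  if (!all(c("date", "deaths") %in% names(df))) {
    stop("mortality file must have columns date, deaths")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stop("unparseable date at row ", which(is.na(df$date))[1])
  }
  for (col in grep("^deaths", names(df), value = TRUE)) {
    x <- df[[col]]
    bad <- which(!is.na(x) & (x < 0 | x != round(x)))
    if (length(bad)) {
      stop(col, " must be a non-negative integer; row ", bad[1])
    }
  }
  if (all(c("deaths_f", "deaths_m") %in% names(df))) {
    bad <- which(df$deaths_f + df$deaths_m != df$deaths)
    if (length(bad)) {
      stop("deaths != deaths_f + deaths_m at row ", bad[1])
    }
  }
  gaps <- which(diff(as.integer(df$date)) > 1)
  if (length(gaps)) {
    warning(length(gaps), " gap(s) in the daily date sequence, first after ",
            df$date[gaps[1]])
  }
  df
}

#' Write a data frame as a plain CSV with ISO dates
#'
#' @param df Data frame; `Date` columns are written as ISO-8601.
#' @param path Output path; directories are created as needed.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on station data
#'
#' Sequences the stages of the historical analysis: PET at the reference
#' hour, adaptive grading, expected-mortality baseline, per-grade
#' sensitivity over the April-October window, and decadal trends per
#' heat-stress grade. All stage outputs plus a manifest (configuration
#' hash, seed, package version) are returned, and written under
#' `out_dir` if given.
#'
#' @param met Met data frame (as from [read_met_csv()] or
#'   [generate_met_series()]).
#' @param mortality Mortality data frame (`date`, `deaths`).
#' @param herate Apply short-term adaptation in grading (default `TRUE`).
#' @param hour,lat,lon Reference hour and coordinates for PET.
#' @param window_start,window_end Analysis window, `"mm-dd"`.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List `pet`, `grades`, `baseline`, `sensitivity` (grade means
#'   over the window, analysis grades), `annual` (annual grade means),
#'   `trends` (per heat-stress grade), `manifest`.
#' @export
run_pipeline <- function(met, mortality, herate = TRUE, hour = 14,
                         lat = 48.25, lon = 16.36,
                         window_start = "04-01", window_end = "10-31",
                         seed = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pet <- stage("pet", pet_series(met, hour = hour, lat = lat, lon = lon))
  grades <- stage("grade", grade_series(pet, herate = herate))
  base <- stage("baseline", mortality_baseline(mortality))

  merged <- stage("merge", {
    m <- merge(base, grades, by = "date")
    m[analysis_window(m$date, window_start, window_end), ]
  })
  sens <- stage("sensitivity",
                grade_means(merged$relative, merged$analysis_grade))
  annual <- stage("annual",
                  annual_grade_means(merged$relative, merged$analysis_grade,
                                     merged$date))
  trends <- stage("trends", {
    out <- list()
    for (g in c("moderate", "strong", "extreme")) {
      a <- annual[annual$grade == g, ]
      out[[g]] <- fit_trend(a$year, a$mean)
    }
    out
  })

  cfg <- list(herate = herate, hour = hour, lat = lat, lon = lon,
              window = c(window_start, window_end), seed = seed,
              n_days = nrow(met))
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(tmp)),
                   package_version = as.character(
                     utils::packageVersion("heatmort")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  unlink(tmp)

  result <- list(pet = pet, grades = grades, baseline = base,
                 sensitivity = sens, annual = annual, trends = trends,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series_csv(grades, file.path(out_dir, "grades.csv"))
    write_series_csv(base, file.path(out_dir, "baseline.csv"))
    write_series_csv(sens, file.path(out_dir, "sensitivity.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
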
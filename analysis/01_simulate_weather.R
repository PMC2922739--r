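#!/usr/bin/env Rscript
# Simulate the station weather (1970-2007) and the four emulated
# regional-model runs (1971-2100), and summarise their climates.
# Finding to check here: the scenario series carry the configured warm
# bias and the stepwise warming across the three future periods.

source("analysis/00_config.R")

met <- generate_met_series(station_config())
year <- as.integer(format(met$date, "%Y"))
summer <- format(met$date, "%m") %in% c("06", "07", "08")

rows <- data.frame(series = "station", period = "1970-2007",
                   mean_ta = mean(met$ta),
                   mean_summer_ta = mean(met$ta[summer]),
                   mean_rh = mean(met$rh), mean_wind = mean(met$wind),
                   mean_cloud = mean(met$cloud))

for (label in names(scenario_specs)) {
  scen <- generate_scenario_series(scenario_config(scenario_specs[[label]]),
                                   PERIOD_STARTS)
  sy <- as.integer(format(scen$date, "%Y"))
  ss <- format(scen$date, "%m") %in% c("06", "07", "08")
  for (p in names(PERIODS)) {
    in_p <- sy >= PERIODS[[p]][1] & sy <= PERIODS[[p]][2]
    rows <- rbind(rows, data.frame(
      series = label, period = paste(PERIODS[[p]], collapse = "-"),
      mean_ta = mean(scen$ta[in_p]),
      mean_summer_ta = mean(scen$ta[in_p & ss]),
      mean_rh = mean(scen$rh[in_p]), mean_wind = mean(scen$wind[in_p]),
      mean_cloud = mean(scen$cloud[in_p])))
  }
}

num <- vapply(rows, is.numeric, logical(1))
rows[num] <- round(rows[num], 2)
write_result(rows, "01_weather_summary.csv")

ref <- rows[rows$series == "station", "mean_summer_ta"]
last <- rows[rows$period == "2071-2100", c("series", "mean_summer_ta")]
message("station mean JJA afternoon temperature: ", ref, " degC")
message("2071-2100 scenario JJA means: ",
        paste(sprintf("%s %.1f", last$series, last$mean_summer_ta),
              collapse = ", "))
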
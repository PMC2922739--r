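# Shared configuration of the analysis scripts. Everything is
# deterministic given the seeds below; daily intermediates are cached
# under scratch/ (disposable), summary tables go to results/.

library(heatmort)

SEED <- 20217L

station_config <- function() {
  generator_config(start_year = 1970, end_year = 2007, seed = SEED)
}

# Emulated regional-model runs: a constant warm bias per model and a
# per-period warming increment per emissions scenario.
scenario_specs <- list(
  `REMO-A1B` = list(seed = SEED + 1L, warm_bias = 1.5, warming = 1.6),
  `REMO-B1`  = list(seed = SEED + 1L, warm_bias = 1.5, warming = 1.0),
  `CLM-A1B`  = list(seed = SEED + 2L, warm_bias = 2.0, warming = 1.8),
  `CLM-B1`   = list(seed = SEED + 2L, warm_bias = 2.0, warming = 1.1)
)

scenario_config <- function(spec) {
  generator_config(start_year = 1971, end_year = 2100, seed = spec$seed,
                   warm_bias = spec$warm_bias,
                   warming_per_period = spec$warming)
}

PERIOD_STARTS <- c(2011, 2041, 2071)
PERIODS <- list(reference = c(1971, 2000), p2011 = c(2011, 2040),
                p2041 = c(2041, 2070), p2071 = c(2071, 2100))

cached <- function(name, expr) {
  dir.create("scratch", showWarnings = FALSE)
  path <- file.path("scratch", paste0("cache-", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- expr
  saveRDS(value, path)
  value
}

station_pet <- function() {
  cached("station_pet", pet_series(generate_met_series(station_config())))
}

scenario_pet <- function(label) {
  spec <- scenario_specs[[label]]
  cached(paste0("scenario_pet_", label), {
    scen <- generate_scenario_series(scenario_config(spec), PERIOD_STARTS)
    pet_series(scen)
  })
}

write_result <- function(df, name) {
  dir.create("results", showWarnings = FALSE)
  write_series_csv(df, file.path("results", name))
  message("wrote results/", name)
}
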
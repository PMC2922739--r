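# heatmort

Quantifying and projecting heat-related mortality for a mid-European
city from daily afternoon meteorology and daily death counts.

The package is aimed at biometeorologists and environmental
epidemiologists who want a tested, reproducible implementation of the
classic station-based workflow: thermal stress is described by the
Physiologically Equivalent Temperature (PET), mortality by percent
deviations from a smoothed expected baseline, and the link between the
two — the *sensitivity* of mortality to each heat-stress grade — is
carried into climate scenarios with and without long-term adaptation.

## The method in brief

- **PET** (°C) is the air temperature of a standard indoor reference
  environment (T~mrt~ = T~a~, v = 0.1 m/s, VP = 12 hPa) in which a
  standard person (male, 35 y, 75 kg, light activity, 0.9 clo) reaches
  the same core and skin temperature as outdoors. It is computed at
  14 h local from air temperature, humidity, wind (reduced to 1.1 m)
  and cloud cover via a two-node human energy balance.
- **Stress grades**: slight / moderate / strong / extreme heat stress
  open at PET = 23 / 29 / 35 / 41 °C. The thresholds shift with the
  exponentially weighted mean PET of the previous 30 days relative to
  the calendar-day climatology (short-term acclimatisation); the
  climate-impact analysis folds slight into a broad acceptability
  grade.
- **Relative mortality** (%) is 100 (D − E)/E, where the expected
  deaths E are a one-year Gaussian-tapered moving average of observed
  counts times a smoothed multiplicative calendar-day factor.
- **Sensitivity** of a grade is the mean relative mortality over its
  April–October days, with 95% CI; decadal trends of the annual means
  are tested by OLS slope t-tests and Mann–Kendall.
- **Projection**: scenario PET series are bias-corrected by percentile
  mapping of the thresholds over 1971–2000; days/year per grade for
  2011–2040, 2041–2070, 2071–2100 are multiplied by a sensitivity that
  is either the historical mean (no adaptation) or the fitted decline
  extrapolated at its most conservative confidence bound, floored at
  zero (adaptation). The product, in percent-days, is the *cumulated
  heat-related mortality* (100 = one day's baseline deaths).

Station mortality and regional-climate-model series of this kind are
generally not redistributable, so the package ships a synthetic-data
module that reproduces the statistical structure of all inputs
(seasonal winter-high mortality over a declining 80 → 50 deaths/day
trend with Poisson noise and multiplicative per-grade heat effects;
sinusoidal + AR(1) weather with summer heat episodes; warm-biased,
stepwise-warming scenario series). The whole pipeline is exercised on
generated data.

## Worked example

```r
library(heatmort)

cfg    <- generator_config(seed = 1)            # 38-year station emulation
met    <- generate_met_series(cfg)              # daily 14 h meteorology
pet    <- pet_series(met)                       # energy-balance PET
grades <- grade_series(pet, herate = TRUE)      # adaptive stress grades
mort   <- generate_mortality_series(grades, cfg)
res    <- run_pipeline(met, mort[c("date", "deaths")], seed = 1)
res$sensitivity
#>        grade   mean ci_low ci_high n_days
#> 1 acceptable -0.744 -1.119  -0.369   4665
#> 2   moderate -0.715 -1.317  -0.114   1822
#> 3     strong  1.760  0.961   2.558   1144
#> 4    extreme  8.020  6.450   9.591    288
```

Reading the output: over the 38 simulated years, April–October days of
extreme heat stress (PET above the adapted 41 °C threshold; 288 days,
about 7.8 per year) carry on average 8.0% more deaths than the
seasonal baseline, days of strong heat stress 1.8% more, while days in
the broad acceptability grade sit slightly below the baseline. The
means are attenuated against the generator's injected effects because
the seasonal baseline absorbs part of the mean summer heat signal — a
structural property of this baseline family discussed in the methods
vignette. `res$trends` holds the decadal trend of each heat grade
(slope per 10 years, CI, both p-values); with the generator's
time-constant effects none is significant, so the adaptation approach
falls back to the end-of-period sensitivity rule.

The scripts under `analysis/` run the full study on the synthetic
inputs — `01_simulate_weather.R`, `02_pet_grades.R`,
`03_mortality_sensitivity.R`, `04_projection.R` — writing summary
tables to `results/`. On the default configuration the four emulated
model runs project +60% to +127% more extreme-heat days per year in
2071–2100 than in 1971–2000, with cumulated extreme-heat mortality
rising by the same relative amounts when no adaptation is assumed.

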
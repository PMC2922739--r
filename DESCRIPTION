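Package: heatmort
Title: Heat Stress and Mortality Analysis with the Physiologically
    Equivalent Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying heat-related mortality from daily
    meteorology and daily death counts, and for projecting it under
    climate scenarios. Computes the Physiologically Equivalent
    Temperature (PET) at a fixed afternoon hour via a two-node human
    energy-balance model, assigns adaptive thermo-physiological stress
    grades with a 30-day acclimatisation rule, derives an expected
    mortality baseline by wide Gaussian smoothing with multiplicative
    seasonal adjustment, estimates per-grade mortality sensitivity with
    confidence intervals and decadal trends (ordinary least squares and
    Mann-Kendall), and projects cumulated heat-related mortality for
    future periods using percentile bias correction of model output,
    with and without long-term adaptation. Includes a synthetic-data
    generator reproducing the statistical structure the analysis
    assumes, so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
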
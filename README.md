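# meadowtherm

Thermal analysis of logger networks in montane meadow streams: quality
control of raw records, a hierarchy of thermal metrics, autocorrelation-aware
comparisons of grazed versus ungrazed reaches, and projection of maximum
water temperatures under air-warming scenarios.

## Who it is for

Stream ecologists and conservation biologists running in-stream temperature
logger campaigns (20-30 min sampling, tens of probes, several summers) in
systems where riparian shading and land use — here, cattle grazing — shape
the thermal habitat of cold-water fishes.

## What it computes

**Metrics.** Per probe: daily minimum / mean / maximum (`DminT`, `DavgT`,
`DmaxT`); seven-day *moving medians* of each (`WminT`, `WavgT`, `WmaxT`),
robust to single aberrant days; and season maxima `MWavgT = max(WavgT)`,
`MWmaxT = max(WmaxT)` — the standard proxies for chronic and acute thermal
exposure.

**Diagnostics.** Moran's I on model residuals with inverse-distance weights
(`w_ij = 1/d_ij`), null expectation `-1/(n-1)`, normal-approximation or
permutation p-values; lag-1 autoregression of aggregated series; polynomial
coordinate adjustment for spatially structured comparisons.

**Grazing contrasts.** Downstream warming gradients of `MWmaxT` per reach
(°C per 100 m, OLS with residual Moran's I attached); vegetation-class
chi-squared tests; willow spacing and height comparisons; logistic shading
contrasts with a 98% solar-exposure threshold; and linear mixed-model
temperature contrasts between meadows at week/month/year aggregation with
Satterthwaite degrees of freedom (`lme4`/`lmerTest`/`emmeans`).

**Projection.** A mixed model `DmaxT ~ WavgT + (1|date)` per meadow; air
warming scenarios scaled to water at 0.5 °C/°C; expected maxima with
50/95/99% normal prediction bands read as 2-, 20- and 100-year recurrence
temperatures.

**Synthetic studies.** `build_study()` generates a full probe network
(diel + seasonal signal, AR(1) daily anomalies with distance-decaying
spatial correlation, shading-dependent amplitudes, downstream gradients of
either sign, out-of-water artifacts, bank willow surveys) so the entire
pipeline is testable without field data. The generator's two headline
parameters are literal contracts: `gradient_per_100m` is the along-stream
gradient of the daily maximum, and `max_vs_avg_slope` is the response of
the daily maximum to the weekly average.

## Worked example

```r
library(meadowtherm)

study <- build_study(sim_params(seed = 7), years = 2010:2012)
study
#> <therm_study> 81 probes in 4 reaches; weeks 24-31, years 2010,2011,2012
#>   653184 temperature records

qc  <- qc_study(study)
met <- study_metrics(qc)

gradient_regression(met$season, study$probes)
#> Downstream gradients of MWmaxT (degC per 100 m)
#>   BigWhitney       -0.084 +/- 0.041  t_19 = -2.06, p = 0.0537
#>   Mulkey_grazed    +0.431 +/- 0.044  t_15 = 9.77, p = 6.79e-08
#>   Mulkey_ungrazed  -0.176 +/- 0.048  t_11 = -3.66, p = 0.00375
#>   Ramshaw          +0.013 +/- 0.025  t_28 = 0.52, p = 0.61
```

The grazed reach warms downstream (+0.43 °C per 100 m here, generated at
+0.41), the fenced exclosure reverses the trend (generated at −0.25), and
the rested meadows are flat — the package's gradient fit recovering the
generator's truth. Projection under the four standard warming scenarios:

```r
dat <- max_avg_table(met$daily, met$weekly, study$probes)
mod <- fit_max_vs_avg(dat)
recurrence_table(mod)[, c("scenario", "meadow", "expected_DmaxT", "hi95")]
```

`expected_DmaxT` is the modelled mean daily maximum after shifting each
meadow's baseline weekly average by the scenario's water delta; `hi95` is
the 20-year recurrence temperature (upper 95% band). The full pipeline —
simulate, QC, metrics, contrasts, projection, plus `summary.txt` and
`run.log` — runs as one call:

```r
run_pipeline(list(seed = 7, out_dir = "out"))
```

or from a shell via the thin wrapper `inst/cli/meadowtherm.R`
(`Rscript inst/cli/meadowtherm.R run --config cfg.yaml --out out --seed 7`).

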
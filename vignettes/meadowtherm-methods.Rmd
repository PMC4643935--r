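---
title: "Thermal metrics, grazing contrasts and warming projections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal metrics, grazing contrasts and warming projections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meadowtherm)
```

# The problem

High-elevation meadow streams that hold cold-water trout are warmed both by
climate and by land use: where cattle graze the banks, shade-giving willows
give way to sedges and grasses, the channel is more exposed to direct sun,
and summer maxima climb from upstream to downstream. meadowtherm packages
the full analysis chain for a network of in-stream temperature loggers in
such systems: quality control, a hierarchy of thermal metrics, comparisons
of grazed and ungrazed reaches that respect spatial and temporal
autocorrelation, and projection of maximum water temperatures under
air-warming scenarios. Because logger campaigns of this kind are rarely
redistributable, the package ships a synthetic study generator with the
statistical structure the analysis assumes, and every stage is tested
against it.

# The metric hierarchy

Loggers record water temperature every 20-30 minutes. Per probe and
calendar day we compute the daily minimum, mean and maximum (`DminT`,
`DavgT`, `DmaxT`); a day is used only if it holds at least 75% of the
records its sampling interval implies (`completeness_frac`, configurable —
the threshold is a pragmatic default, not an estimate). The "weekly"
metrics `WminT`, `WavgT`, `WmaxT` are *medians* of the daily values over
seven-day moving windows, so a single aberrant day (a probe briefly out of
the water, an electronic glitch) cannot move them. The season maxima
`MWavgT = max(WavgT)` and `MWmaxT = max(WmaxT)` summarise each probe's
warmest consecutive week; they are the standard proxies for chronic
(sub-lethal) and acute (lethal) thermal exposure.

Two conventions are deliberately configurable because the field does not
agree on them:

* **Window alignment.** The moving window is centred (days −3..+3) by
  default, with at least `min_days = 4` valid days; trailing alignment is
  available (`align = "trailing"`). Centred alignment keeps the median on
  top of the data it summarises.
* **Week numbering.** The summer analysis window (weeks 24-31, mid-June to
  early August) uses ISO-8601 week numbers by default;
  `week_convention = "ordinal"` (`ceiling(yday/7)`) is available. The two
  differ by at most a few days at the window edges.

With several summers of data the season maxima are taken over the whole
study duration by default (`by = "overall"`); `per_year` is available.
Median of an even day count is the mean of the two central values.

# Quality control

Out-of-water days are removed *whole*: a flagged calendar day loses every
record, never a subset, and the operation is idempotent. The primary
mechanism is explicit flags (field notes, or the synthetic injector); a
range-based heuristic (`flag_out_of_water()`, daily range above 15 °C) is
provided but not applied automatically, since such decisions are usually
made by a person looking at the trace. Timestamps are treated as local
clock time with day boundaries at midnight; no DST arithmetic is applied.

# Autocorrelation diagnostics

Thermal series are autocorrelated in time (records minutes apart), in
space (probes along one channel), and by repetition (the same probe all
summer). Ignoring this does not bias effect estimates but understates
their uncertainty. The package's diagnostic is Moran's I on model
residuals with inverse-distance weights,

$$ I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
   \qquad w_{ij} = 1/d_{ij}, $$

with expectation $-1/(n-1)$ under the randomization null, the standard
randomization variance, and a seeded permutation option for small n.
Distances are great-circle metres for coordinates and absolute differences
for transect positions or times; coincident points are floored at half the
smallest positive distance. Row-standardization is off by default — the
statistic is the explicit double sum — and the test suite pins the
implementation to a brute-force oracle and cross-checks the normal
approximation against an independent reference implementation (which
row-normalizes; the comparison accounts for that).

Where residual spatial structure is found, group comparisons are adjusted
by including the coordinates and their squares as covariates
(`autoregressive_adjusted_model()`), which is a polynomial-trend
adjustment, not a spatial-likelihood model (SAR/CAR estimation is out of
scope).

# Grazing contrasts

* `vegetation_type_test()`: Pearson chi-squared (no continuity
  correction) on the treatment-by-vegetation table.
* `binarize_solar()` / `shade_logistic()`: solar exposure is binarized at
  98% ("essentially unshaded"), and the sunny share compared between
  treatments by logistic regression, with complete separation detected and
  Fisher's exact test as fallback.
* `willow_spacing()` / `willow_heights()`: consecutive gaps along the bank
  and truncated heights per treatment, each compared with the
  polynomial-adjusted model.
* `gradient_regression()`: per-reach OLS of `MWmaxT` on along-stream
  distance, reported in °C per 100 m, with residual Moran's I attached.
  Reaches are fitted separately — a pooled ANCOVA is wrong here because
  the slopes genuinely differ in sign between treatments.
* `aggregate_metric()` + `compare_groups_lmm()`: weekly metrics are
  averaged into week/month/year cells and compared between groups with a
  linear mixed model (`lmerTest`), random intercept for the time unit,
  pairwise contrasts with Satterthwaite degrees of freedom (`emmeans`).

## The aggregation trade-off, and which mode to trust

Aggregating at coarser time scales removes temporal autocorrelation at the
cost of power; the package reports all three scales so the trade-off is
visible, and the acceptance suite demonstrates it directly: on null data
whose daily values are AR(1), the month-scale contrast's type-I error sits
at the nominal 5% while the week-scale contrast is inflated — adjacent
weekly cells share days through the 7-day moving window, so their errors
are correlated.

Two aggregation modes exist because the underlying designs differ:

* `per_reach` (one value per river and time unit) is the conservative
  analysis. Its residual is exactly the river-by-month fluctuation, so its
  standard errors are honest for contrasts between rivers.
* `per_probe` keeps probes and adds a probe random intercept. Its
  fractional degrees of freedom match the repeated-measures style of
  reporting, and it is the interface default; but when each group *is* one
  river, a river-level anomaly shared by all its probes is invisible to
  the probe and month random effects, and the contrast standard errors are
  anti-conservative. The package's own calibration checks therefore use
  `per_reach`; treat `per_probe` month-scale standard errors for
  river-level contrasts with caution. This is the same repeated-measures
  caveat that motivates the aggregation in the first place.

# Warming projection

`fit_max_vs_avg()` regresses the observed daily maximum on the weekly
average per meadow, with a calendar-date random intercept for repeated
measures ("date" is the calendar day shared by all probes, which is what
repeated measurements across the network share). The slope says how much
the hottest moment of a day rises per degree of weekly average warming; a
slope above 1 means maxima amplify mean warming. An all-meadow interaction
model supplies slope differences between meadows with Satterthwaite
degrees of freedom. Degenerate fits (zero residual variance, as in
noise-free simulations) fall back to OLS and are flagged.

Scenarios specify an air-temperature increase, converted to water at a
fixed conservative ratio of 0.5 °C per °C. The four standard scenarios
(0, +1, +3.7, +5.6 °C air) use the conventionally reported one-decimal
water deltas (0, 0.5, 1.8, 2.8 °C); `exact_products = TRUE` recomputes
them at full precision (1.85 instead of 1.8). `project_scenario()` shifts
the meadow's baseline mean `WavgT` by the water delta and reports

$$ \widehat{DmaxT} = a + b\,(\bar W + \Delta_w) \pm z\,\sigma_{tot},
   \qquad z \in \{0.674, 1.960, 2.576\}. $$

The band standard deviation defaults to
$\sigma_{tot} = \sqrt{\sigma^2_{resid} + \sigma^2_{date}}$ — the bands
describe across-day, across-site extremes, so the date-to-date variance
belongs in them; `sd_mode = "residual"` is available. The 50/95/99% upper
limits are read as the 2-, 20- and 100-year recurrence temperatures. That
reading is kept as conventionally stated even though a two-sided 95% upper
limit is strictly a 2.5% exceedance; the package documents rather than
"corrects" the convention. Rendered tables round half-up to one decimal;
machine outputs keep full precision. The Mulkey grazed/ungrazed probes are
pooled by default for this analysis (the conservative choice for a
partially grazed meadow); `pool_mulkey: false` restricts to grazed probes.

# The synthetic study generator

No generative model is claimed by the field study this package is built
around; the simulator is the minimal structure exhibiting the phenomena
the analysis must detect. Per probe and day $d$:

$$ m_d = \mu_{meadow} + \frac{g/s}{100}(x - L/2) + \text{season}(d), \qquad
   M_d = m_d + \alpha_d, $$

$$ W_d = \mathrm{runmed}_7(M_d), \qquad
   A_d = \max\left(A_{min},\; A_{base} + (s-1)(W_d - T_{ref}) - (M_d - W_d)\right), $$

$$ T(t) = M_d + A_d \cos\!\left(\tfrac{2\pi (h - 16)}{24}\right) + \varepsilon(t). $$

Design choices worth knowing:

* **The two headline parameters are literal contracts.** The day's peak is
  $M_d + A_d = A_{base} + s\,W_d - (s-1)T_{ref}$, so the daily maximum
  tracks the running weekly median with slope exactly
  `max_vs_avg_slope` $= s$ for *every* source of variation, and
  `gradient_per_100m` $= g$ is the along-stream gradient of the daily
  *maximum* (the scale on which downstream warming is reported); the
  mean-level gradient is $g/s$. The $-(M_d - W_d)$ term acts like thermal
  inertia — days warmer than their surrounding week swing slightly less
  about their mean. Without this anchoring, the fitted slope drifts with
  the noise structure and the generator's parameters would be tendencies,
  not recoverable truths.
* **Noise.** $\alpha_d$ is a daily anomaly field on a fixed 25 m grid per
  meadow: AR(1) across days (`ar1_phi`, default 0.6), exponential spatial
  correlation along the stream (`spatial_range`, default 200 m),
  stationary sd `noise_sd` (default 0.5 °C). Because the field is seeded
  by meadow and year — never by the probe set — adding a probe cannot
  perturb any other probe's series. Record-level noise $\varepsilon$ is
  AR(1) at the sample scale with a 3 h correlation time (water is smooth
  at 30 minutes); with *white* record noise the expected maximum of the
  48 noisy samples would depend on the diel amplitude and bias the
  max-vs-avg slope by about half a percent. Even so, `DmaxT` is the
  maximum of noisy records and carries a small positive offset; parameter
  recovery checks therefore switch record-level noise off and let the
  daily anomaly carry the stochasticity.
* **Season.** A half-sine hump spanning the peak week ±6 weeks, centred so
  that `meadow_means` are approximately the window means of `WavgT`; the
  default amplitude (2 °C) gives the within-summer variation the
  projection model needs for identification.
* **Shading** acts on the diel amplitude only (3.5 °C sunny vs 2.0 °C
  shaded by default, switching at 98% solar exposure); an optional
  `shading_mean_effect` shifts the mean for sensitivity work. Shading
  reduces direct heat transfer, i.e. the day's swing, before it moves the
  daily mean.
* **Willows** are uniform along the bank with truncated-normal heights;
  defaults give ~980 stems over 1200 m (0.92 ± 0.56 m tall) inside the
  exclosure versus ~75 over 900 m (0.43 ± 0.29 m) outside. Field surveys
  suggest stem clustering; uniform positions cannot match both the counts
  and the observed mean spacing simultaneously, and the generator does not
  try (`clustered = TRUE` exists but is off by default).
* **Out-of-water artifacts** replace a day's records with an air-like
  swing rescaled to 2.2× the largest clean daily range, guaranteeing the
  QC heuristic's detection margin deterministically.

## What the generator does and does not emulate

It reproduces diel and seasonal structure, downstream gradients of either
sign, meadow offsets, temporal and spatial autocorrelation, amplitude
shading effects, and out-of-water artifacts. It does **not** model the
heat budget (solar radiation, evaporation, hyporheic exchange), tributary
mixing, groundwater inputs, flow dependence, or non-Gaussian extremes.
Passing recovery tests therefore shows the *estimators* are correct under
the assumed structure — not that real meadow streams obey it.

## Problem sizes and calibration conditions in the test suite

The acceptance suite simulates a 17-probe grazed reach over one summer for
gradient recovery (100 replicate seeds, fixed bank 1-100), three
six-probe meadows over three summers for contrast recovery (seed bank
1-12), and 200 null replicates for the type-I calibration; these sizes
give Monte-Carlo standard errors a few times smaller than the effects
under test while keeping the default test run in minutes. Two conditions
in those suites differ deliberately from the network defaults:

* probes are amplitude-homogeneous (`diel_amplitude_shaded = sunny`),
  because the sunny/shaded amplitude offsets act as probe-level intercept
  noise that can correlate with position in small networks and tilt pooled
  slopes — realistic, but not a parameter-recovery condition;
* the gradient suite uses `spatial_range = 10` m, well below the ~56 m
  probe spacing, so regression residuals are independent across probes.
  With the 200 m default, OLS coverage collapses (to ~67% in pilot runs)
  — the textbook spatial-autocorrelation failure — and even 30 m leaves a
  0.15 neighbour correlation and visibly depressed coverage. Field
  analyses of this design justify OLS by showing near-zero residual
  Moran's I, and the recovery suite emulates exactly that condition; the
  200 m default remains for demonstrating the spatial diagnostics
  themselves.

Statistical assertions use pre-set binomial tolerances: coverage of a 95%
interval over 100 seeds is asserted at ≥ 91/100 (the one-sided 5% point
of Bin(100, 0.95)) — demanding ≥ 95/100 would fail almost half the time
for a perfectly calibrated estimator — and null rejection at ≤ 12/100.

# Numerical conventions

* Ties in rendered reports round half away from zero (`round_half_up()`),
  so 26.75 prints as 26.8.
* Degenerate mixed fits (residual sd below $10^{-6}$ of the response
  spread) fall back to exact OLS/group-mean computations and are flagged
  `singular`; p-values from a mixed model whose Satterthwaite denominator
  has collapsed are meaningless and are never reported.
* Machine outputs (CSV) carry full double precision (`%.17g` for logger
  round-trips), which is what makes skip-simulate re-runs bit-identical.
* All randomness flows from one root seed through a stable string hash
  (31-adic, mod $2^{31}-1$), giving independent per-probe, per-meadow and
  per-stage streams.

# Known limitations

* The projection is a linear air-to-water shift applied to a linear
  max-vs-avg response; no nonlinear (logistic-type) transfer function.
* Recurrence labels inherit the convention described above.
* `per_probe` contrast standard errors are anti-conservative for
  river-level effects (see the aggregation section).
* The generator's willow module cannot match count and spacing jointly
  under uniform positions.
* Moran's I with raw inverse-distance weights has low power against
  smooth linear trends when probes cluster (a few very close pairs
  dominate $S_0$); the permutation option does not change this, it is a
  property of the weight rule.
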
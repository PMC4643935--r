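Package: meadowtherm
Title: Thermal Metrics, Grazing Contrasts, and Warming Projections for
    Meadow Stream Logger Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing networks of in-stream temperature loggers
    in montane meadow streams. Provides quality control of logger records
    (out-of-water removal, summer-window selection), a hierarchy of thermal
    metrics (daily minima/means/maxima, seven-day moving medians, and season
    maxima used as chronic and acute exposure proxies), Moran's I
    autocorrelation diagnostics with inverse-distance weights,
    autocorrelation-aware comparisons of grazed versus ungrazed reaches
    (downstream warming gradients, vegetation and shading contrasts,
    mixed-model temperature contrasts with Satterthwaite degrees of
    freedom), and projection of maximum water temperatures under air-warming
    scenarios with recurrence-interval bands. A synthetic logger-network
    simulator with diel and seasonal signal, AR(1) noise, and
    distance-decaying spatial correlation supports testing of the full
    pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
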
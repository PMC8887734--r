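Package: tickcast
Title: Ensemble Forecasting and Data Assimilation for Tick Paralysis Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for near-term forecasting of seasonal veterinary admission
    counts, built around canine tick paralysis caseloads. Provides fortnightly
    binning and deduplication of clinical case records, STL seasonal adjustment,
    engineered environmental predictors with data-driven lag selection, four
    covariate-driven forecast members (regression-ARIMA, a Bayesian
    heteroskedastic moving-average regression, a negative-binomial GAM and a
    decomposable piecewise-trend regression), an interval-score-optimized convex
    ensemble, Sequential Monte Carlo particle filtering for assimilating
    incoming observations without refitting, and rolling-origin evaluation
    against an exponential-smoothing benchmark. A synthetic-data generator with
    known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
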
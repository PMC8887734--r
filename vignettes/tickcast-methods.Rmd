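---
title: "Forecasting seasonal admission counts with tickcast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seasonal admission counts with tickcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tickcast forecasts strongly seasonal veterinary admission series — its
motivating application is canine tick paralysis caseloads in subtropical
eastern Australia — from a clinical case line list and a table of
area-aggregated environmental covariates. This vignette explains the models,
the tunable parameters and the design decisions, in the spirit of a methods
appendix. Nothing here states an empirical result that the package's tests or
the acceptance script do not themselves compute.

## The data model

The unit of analysis is the *fortnight*: each calendar month is split at day
15/16 into two bins, giving 24 bins per year. Months have 28–31 days, so
exactly even halves are impossible; the 1–15 / 16–end convention is fixed and
used everywhere (`fortnight_of_date()`, `bin_fortnights()`).

Case records carry an admission date, a clinic label, a species and a record
class (confirmed / probable / improbable). Records are deduplicated per
(clinic, species) stream with a greedy forward pass: a record dated within
`window_days` (default 14, one fortnight) of a retained record is treated as a
re-presentation of the same animal and dropped. Records carry no animal
identity, so at high caseloads the rule can also collapse genuinely distinct
admissions in the same stream; this is inherent to identity-free
deduplication and is visible in the synthetic generator's bookkeeping.
Improbable records are *not* filtered: retrieval is assumed roughly 95%
specific, and misclassified records are simply part of the observation
process.

## Seasonal adjustment and stationarity

`stl_decompose()` performs an additive STL split (via `stats::stl`) into
seasonal, trend and remainder components; the three components sum to the
input exactly. The seasonal Loess span defaults to 25 — a large window giving
a near-periodic, slowly evolving seasonal shape — and is exposed, as is the
trend span; robust fitting is off by default. The *seasonally adjusted*
series is trend + remainder (`seasonally_adjust()`), the working scale for
the two time-series members and the particle filter.

`adf_test()` is an augmented Dickey–Fuller regression written on top of
`lm.fit`: the change in the series is regressed on its lagged level, a
constant, optionally a linear trend, and AIC-selected lagged differences
(compared on a common sample). P-values interpolate the standard tabulated
percentiles of the Dickey–Fuller t-distribution in both the sample size and
the statistic, clamping (with a warning) outside the tabulated 0.01–0.99
range. The default specification includes the linear trend; a constant-only
("drift") variant is selectable. The implementation is checked in the test
suite against a frozen reference value computed independently with Python
statsmodels on an identical series.

## Engineered predictors

From the raw covariate table (maximum/minimum temperature, rainfall,
evapotranspiration, NDVI, SOI, shrub and forest cover) the package builds
nine candidates (`engineer_covariates()`):

* a **moist vegetation** index. The default convention is the product form
  `rainfall * (-evapotranspiration) * (shrub + forest)`; a water-balance
  convention `(rainfall - evapotranspiration) * (shrub + forest)` — which
  increases with rainfall and decreases with evapotranspiration, the
  ecologically intuitive direction — is available via an argument, because
  the two conventions genuinely disagree and the choice is left to the
  analyst.
* **quarterly anomalies** of moist vegetation, the temperatures and NDVI.
  The anomaly for a fortnight is the mean of its calendar quarter (that
  year) minus the long-term mean of that quarter, so it is constant within a
  year-quarter and zero for a series that repeats identically every year.
  Long-term quarter means use the training window only, preventing leakage
  into validation. A consequence worth knowing: anomaly values are finalized
  only once their quarter completes; while a quarter is in progress its
  anomaly is the quarter-to-date contrast.
* the raw temperature and NDVI series and the fortnightly SOI.

`prune_collinear()` then drops candidates greedily while any retained pair
has |Pearson r| above 0.70, keeping the higher-priority member of the
offending pair. The priority list is explicit configuration rather than an
ad hoc re-derivation; the default ordering keeps maximum temperature over
minimum temperature and an anomaly over its raw NDVI series.

`select_lags()` picks, for each retained covariate, the lag in 1–6 fortnights
(2–12 weeks) whose lagged values have the strongest absolute cross-correlation
with the seasonally adjusted series, ties resolved toward the smaller lag,
then scales each lagged predictor to unit variance on the training window.
Because every predictor enters at lag ≥ 1, forecasts up to the minimum
selected lag need no covariate extrapolation; beyond that, last-value
persistence is available behind an explicit flag.

## The four ensemble members

All members emit the same representation: `S` sample trajectories per horizon
(default 1000), summarized by the median and central 80%/95% intervals
(`forecast_distribution`). A sample-path representation lets the ensemble and
the particle filter share one machinery.

**Regression-ARIMA** (`fit_arima_seasadj`): on the seasonally adjusted
series, a grid over covariate subsets of size 0–5 with automatically chosen
(p, d, q) orders, minimizing in-sample BIC, Gaussian innovations. The search
is staged to stay tractable: orders are tuned on the covariate-free model,
all subsets are compared at those orders, and orders are re-tuned for the
winning subset. Forecast paths simulate the ARMA recursion and include
sampling uncertainty of the regression coefficients (multivariate normal on
the estimated covariance); ARMA-coefficient uncertainty is not propagated,
as innovation variance dominates at these sample sizes.

**Heteroskedastic Bayesian regression** (`fit_garch_seasadj`): mean =
intercept + MA(2) on past innovations + linear covariate effects; conditional
variance = `a0 + a1*eps[t-1]^2 + a2*eps[t-2]^2`, so both the mean and the
variance are driven by two moving-average lags. All predictors enter
simultaneously with regularizing Laplace priors (mean 0, sd 0.5). Estimation
is Gibbs sampling via JAGS — four chains of 1000 draws after adaptation and
burn-in, pooled and thinned to 1000 retained draws. Convergence is summarized
by the largest split R-hat; fits at R-hat ≥ 1.05 are flagged and should be
excluded from the ensemble. Forecast paths are posterior predictive: each
trajectory carries one posterior draw and its implied terminal innovations.

**Negative-binomial GAM** (`fit_gam_raw`, via mgcv): raw counts with a log
link; an unpenalized cubic spline of time-in-years for the nonlinear trend, a
cyclic cubic smooth of fortnight (endpoints matched at the year boundary) for
seasonality, and a shrinkage-penalized smooth (`bs = "cs"`) per predictor so
uninformative predictors are selected out (their effective degrees of freedom
shrink toward zero). The NB overdispersion φ — variance `mu + mu^2/phi` — is
estimated alongside by REML (the NB family requires a likelihood-based
smoothness criterion). Residual moving-average autocorrelation is estimated
post hoc and reported rather than embedded in the fit: an NB mixed-model
fit with an MA residual process is numerically fragile at these counts, and
the forecast paths draw NB observation noise per horizon. Forecast paths
combine multivariate-normal draws of the spline coefficients with NB
observation draws.

**Decomposable piecewise-trend regression** (`fit_prophet_raw`): a
Prophet-style Gaussian model on `log(count + 1)`: piecewise-linear trend with
25 evenly spaced candidate changepoints over the first 80% of the series,
slope changes shrunk by a sparse Laplace prior (scale 0.50, loosened from the
conventional 0.05 to allow flexible trends); Fourier seasonality (order 10 on
the 24-fortnight year) with a Gaussian prior; additive linear regressors.
The three regressors (configurable) with the lowest single-regressor deviance
against a trend + seasonality base model are retained. Fitting is by MAP
(penalized least squares with a smoothed L1 term, BFGS, with the noise scale
re-estimated once); forecast uncertainty combines observation noise with
generative future-changepoint simulation at the historical changepoint
frequency and fitted magnitude scale. A full-MCMC treatment would be the
natural extension; MAP plus generative trend uncertainty is the package's
design choice and keeps the member dependency-free.

**Exponential smoothing** (`ets_fit` / `fit_ets`): a compact additive
innovations state-space family (ANN/AAN/ANA/AAA) with smoothing parameters
and initial level/trend estimated by Gaussian one-step likelihood, initial
seasonal states from a classical decomposition of the early cycles, and the
component structure chosen by AIC. It serves twice: as the benchmark
forecaster on `log(count + 1)` (back-transformed with `expm1` and truncated
at zero), and as the seasonal-component forecaster that restores seasonality
to the seasonally adjusted members.

Seasonally adjusted forecasts move to the outcome scale by *pathwise*
addition of seasonal forecast paths (`to_outcome_scale`), treating the two
uncertainties as independent, then truncate at zero — negative admissions are
meaningless. Truncation at zero is applied after every back-transform or
combination on the count scale.

## Interval scoring and the convex ensemble

A 95% interval (L, U) scored against observation Y earns
`(U - L) + c (L - Y) 1[Y < L] + c (Y - U) 1[Y > U]`. The standard penalty is
`c = 2/alpha` (alpha = 0.05), rewarding narrow intervals that still contain
the observation; a `c = 2*alpha` variant is selectable because the two
conventions produce different optimizer solutions and both are worth testing.
Under the `2/alpha` convention the score is translation-equivariant.

`optimize_weights()` minimizes the mean interval score of the weighted member
intervals (quantile averaging: the combined bound is the weighted mean of the
member bounds) over a validation window, on the probability simplex. The
simplex is handled by a softmax reparameterization with multi-start
optimization (25 restarts, seeded); every corner (single member) and the
equal-weight point are always evaluated directly, so the optimized score can
never exceed the best single member's — a property the test suite asserts on
randomized instances, alongside equivalence with an exhaustive 0.01-step
simplex grid search for up to three members. Weights are constant across
horizons; time-varying weighting is out of scope.

## Sequential Monte Carlo assimilation

For the two seasonally adjusted members, incoming observations are
assimilated without refitting. `init_particles()` draws N (default 5000)
trajectories from the fitted model's simulation with uniform weights. Each
`assimilate()` step propagates every trajectory one fortnight through the
member's equations, evaluates the Gaussian log-likelihood of the observation
given the particle's proposal (scale `obs_noise_sd`, initialized from the
member's residual sd), and *adds* it to the particle's accumulated
log-weight — the condensation product of likelihoods, kept in log space
because the verbatim product underflows within a handful of steps.

When the effective sample size `1/sum(w^2)` falls below half of N (the
threshold fraction is configurable), `maybe_resample()` draws N particles
with replacement in proportion to their weights (multinomial by default;
systematic resampling is available), adds Gaussian random-walk jitter of
scale `mutation_sd` (default 10% of the observation scale — "small" is
necessarily a judgement call) to each resampled trajectory state to restore
diversity, and resets weights to uniform. Mutation perturbs trajectory states
only; coefficient drift is deliberately not performed. Observed counts are
converted to the assimilation scale by subtracting the STL seasonal component
extended by the seasonal exponential-smoothing forecast.

Two exactness properties anchor the implementation and are tested: with
mutation off and resampling effectively disabled, the filter is exact
sequential importance sampling (accumulated log-weights equal the summed
per-step log-likelihoods); and on a linear-Gaussian AR(1) state-space model
the filtered means and variances match the closed-form Kalman filter within
Monte-Carlo error that shrinks as N grows.

Clinic-level adaptation (`adapt_to_subseries`) reuses all aggregate-fit
parameter distributions per clinic, re-initializing only the Gaussian
observation-error scale from the residual sd of an ARIMA(1,0,1) fit to the
clinic's seasonally adjusted series, and assimilates the clinic series from
its start (trajectory levels re-initialized to the clinic's early mean).

## Evaluation protocol

`train_test_split()` takes the first `ceiling(0.85 T)` observations for
training; held-out bins before the final calendar year are the
weight-optimization validation window and the final year is the test window.
For an 11-year series this gives 264 bins, 225 training and 39 held out.

`rolling_evaluate()` advances the training cut-point fortnight by fortnight.
At each origin everything downstream of the raw data — STL, anomaly
climatology, collinearity pruning, lag selection, scaling, member fits — is
recomputed from data up to the origin only; a bit-identity test (perturb
post-origin data, compare reports) enforces this. The ARIMA member reuses
the orders and covariate subset selected at the first origin and refits
coefficients only, mirroring how a deployed system would re-estimate rather
than re-specify. Scores are the 95% interval score and the absolute error of
the forecast median ("point error"; the median is the natural point summary
of an interval forecast, and a mean-based alternative would change nothing
structural). Horizon bands are near-term 1–6 fortnights (2–12 weeks) and
medium-term 6–12 fortnights (12–24 weeks); fortnight 6 belongs to both
because the bands share week 12.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates: 11 years of
fortnightly counts, ~520 retained cases (baseline 1.2 admissions per
fortnight at seasonal factor 1), a Gaussian-bump seasonal profile on the log
scale peaking in fortnights 19–20 (early–mid October, normalized to
geometric mean 1), a piecewise-linear log-trend with a mid-series trough,
NB overdispersion φ = 2, lagged covariate effects of realistic magnitude on
unit-scaled predictors (SOI +0.11 at lag 2, maximum temperature −0.37 at lag
2, moist vegetation +0.05 at lag 6), a 45% re-recording rate (so ~800 raw
records reduce to ~520), and a 5% improbable-record rate with misclassified
records spread uniformly over the year so they dilute seasonality the way
real misclassification would. Climate covariates are seasonal means plus
AR(1) noise (lag-1 correlation 0.6); the SOI is a zero-mean AR(1) with
correlation 0.9; cover proportions change only between years. Ground truth
(per-fortnight means and true counts) is returned as a separate table so
pipeline code can never consume it by accident.

What the generator does *not* emulate: spatial structure within the study
area, covariate measurement error, reporting delays, multi-year tick
population cycles, and animal identity (so deduplication can collapse
genuinely distinct same-stream admissions at high caseloads). Tests passing
on this generator therefore demonstrate the correctness of the machinery and
the recoverability of injected structure — not field performance.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant series are rejected by the
Dickey–Fuller regression and produce flat exponential-smoothing forecasts;
zero-variance covariates are rejected by lag selection; all-zero counts are
rejected by the GAM; lag-selection ties break toward the smaller lag;
interval bounds are validated (`L <= U`) before scoring. The softmax weight
parameterization makes the simplex constraint exact by construction.

The test suite runs everything at deliberately modest sizes — single fits at
n = 150–500, 20 replicates for coefficient recovery, 10 replicates for the
assimilation-benefit experiment, N = 5000 particles for the Kalman
comparison, 2000 elsewhere — chosen so the whole suite completes in about a
minute while keeping Monte-Carlo error far below the tested tolerances. The
acceptance script (`scripts/acceptance.R`) runs the full pipeline once at
study scale (264 fortnights, four members, 1000 forecast paths, 5000
particles) in under two minutes.

## Known limitations

* The decomposable-trend member is MAP-fit; its seasonality and regressor
  uncertainties are not propagated (only trend-changepoint and observation
  noise are). Its intervals are therefore somewhat narrow, which the
  interval-score weighting penalizes naturally.
* The GAM's residual MA structure is reported, not modelled.
* Anomaly predictors are finalized only at quarter end (see above).
* The exponential-smoothing family is additive-only (no multiplicative error
  or damped trend); on `log1p` counts the additive family is usually an
  adequate surrogate for multiplicative behaviour on the raw scale.
* The benchmark's multiplicative-style intervals (via the `log1p`
  back-transform) are strong in the low season; whether the covariate-driven
  ensemble beats it on interval score in any given synthetic world depends on
  the injected effect sizes, which is why the acceptance script reports the
  contrast rather than the package asserting it.
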
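---
title: "Models and methods behind airmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind airmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package estimates

`airmort` implements a two-stage multi-city time-series analysis of
short-term fine particulate matter (PM2.5) exposure and daily all-cause
mortality, in the design used by multi-city studies of Indian and other
highly polluted urban populations. The quantity of interest is the percent
change in daily deaths per 10 µg/m³ increase in the 2-day moving average
(lag 0–1) of city-wide PM2.5, together with a pooled nonlinear
exposure–response curve and the fraction of deaths attributable to
concentrations above a reference such as the WHO 24-h guideline
(15 µg/m³) or the Indian 24-h standard (60 µg/m³).

Four estimators are chained:

1. a city-specific quasi-Poisson regression with a penalised seasonal
   spline (`fit_quasipoisson()`),
2. an instrumental-variable (IV) estimator of the effect of *locally
   generated* PM2.5, built from three meteorological instruments
   (`iv_effect()`),
3. random-effects meta-analysis of city estimates, univariate
   (`pool()`) and multivariate over spline coefficients
   (`mvmeta_pool()`), and
4. attributable-fraction estimation from the integrated curve with
   Monte-Carlo confidence intervals (`monte_carlo_ci()`).

Because the mortality registries behind such studies are access-restricted,
the package carries a first-class synthetic data module
(`city_scenario()`, `generate_city()`) whose ground truth is known, so
every stage is testable end to end.

# Stage 1: the city-specific regression

For one city with daily deaths $Y_t$ and lagged exposure $x_t$,

$$\log E(Y_t) = \alpha + s(t) + \mathrm{DOW}_t + f(\mathrm{temp}_t) + \beta x_t,
\qquad \mathrm{Var}(Y_t) = \phi\, E(Y_t),$$

where $s(t)$ is a seasonal/long-term spline of calendar day,
$\mathrm{DOW}$ are day-of-week indicators (reference Monday, an arbitrary
choice that affects nothing reported), $f$ is a natural cubic spline with
4 df of the lag 0–4 moving average of daily mean temperature (interior
knots at equally spaced quantiles, boundary knots at the observed range),
and $\phi$ is the quasi-Poisson dispersion. The default exposure metric is
the lag 0–1 moving average; single lags 0, 1, 2 and the lag 0–3 average
are available through `lag_spec()` and `run_lag_panel()`. Days whose lags
are undefined are dropped, not imputed — the standard convention, costing
at most four days.

## The penalised seasonal spline and its df target

The seasonal term is specified by its effective degrees of freedom:
9 df per year by default, with 6–10 df/year as the sensitivity range.
We read "penalised spline with a fixed df budget" in the way generalized
additive modelling practice does: a cubic B-spline basis *larger* than the
budget (the budget plus 10 columns, sum-to-zero constrained against the
intercept), a ridge penalty on squared second differences of the
coefficients, and a smoothing parameter $\lambda$ *solved* — not chosen by
a criterion — so that the block's effective df,
$\mathrm{tr}\{(X^\top WX + \lambda S)^{-1} X^\top WX\}$ restricted to the
seasonal columns, equals the budget. A basis exactly equal to the budget
would make the penalty vacuous ($\lambda = 0$); the spare columns are what
the penalty shrinks away. The 1-D root-find on $\log\lambda$ is iterated
with the IRLS working weights until both are stable.

Fitting is penalised iteratively reweighted least squares with log link:
relative deviance change below $10^{-8}$ or 50 iterations, deterministic
at double precision. The dispersion is the Pearson statistic over
$n - \mathrm{edf}$, where edf is the trace of the full hat contribution
including the penalised block; all standard errors scale by $\sqrt{\phi}$,
and the exposure coefficient's variance uses the sandwich form
$\phi\,(X^\top WX+\lambda S)^{-1} X^\top WX\,(X^\top WX+\lambda S)^{-1}$,
which collapses to the familiar GLM covariance when nothing is penalised
(the configuration `cov_spec(time_penalized = FALSE)` used for oracle
comparisons). Effects are reported as
$100\{\exp(10\beta)-1\}$ percent per 10 µg/m³ with normal 95% intervals.

# Stage IV: locally generated pollution

Three meteorological variables instrument the locally generated share of
PM2.5: planetary boundary layer height (low PBLH traps local emissions),
wind speed (low wind limits dispersion) and surface pressure (high
pressure suppresses mixing). Each is lagged like the exposure. The
procedure:

1. regress the lagged exposure on the *confounder* design only (ordinary
   least squares; a projection needs no penalty counterpart) and keep the
   residuals — exposure variation free of season, trend, temperature and
   weekday;
2. fit an epsilon-insensitive support-vector regression with Gaussian
   radial kernel (`e1071::svm`; cost 1, epsilon 0.1, kernel width
   1/3 on standardized inputs — the reference defaults, recorded in the
   output) of the residuals on the three standardized instruments;
3. use the fitted values — the "pollution-calibrated instrument", on the
   µg/m³ scale — as the exposure in the stage-1 regression.

## Why the fitted values need a linear calibration

Epsilon-insensitive SVR shrinks the *amplitude* of its fitted values: the
epsilon tube absorbs small variation and the cost parameter regularises
the rest. If the instrument is an amplitude-shrunk copy of the true local
signal, $\hat g = c\,L$ with $c<1$, the second-stage slope inflates by
exactly $1/c$ — in our simulations roughly a factor of two at training
$R^2$ between 0.2 and 0.5. The claim that the IV effect is "on the PM2.5
scale" is only true of an unshrunk instrument. `calibrate_instrument()`
therefore (by default, and recorded in the hyperparameter log) rescales
the fitted values by the ordinary least-squares slope of the residuals on
the *design-orthogonalized* fitted values, and returns the orthogonalized,
rescaled series. Orthogonalization matters because the kernel fit is free
to carry seasonal structure even though the residuals have none; the
second-stage regression adjusts the instrument for the same confounders,
so the partial slope — not the marginal one — is the relevant scale. Two
consequences, both verified in the test suite: the instrument is exactly
uncorrelated with every confounder column, and in unconfounded simulations
the IV estimate agrees with the conventional one.

In-sample fitted values mirror the plug-in procedure as described in this
literature; `cross_fit = k` switches to contiguous-block cross-fitting,
which removes the overfitting channel by which an unmeasured confounder's
imprint on the residuals can leak into the instrument. The residual
leakage of the in-sample default is visible in the package's
de-confounding simulation: the IV estimator removes most, not all, of a
strong unmeasured confounder's bias. When the generator gives instruments
a direct path to mortality, the IV estimate is biased — the exclusion
restriction is an assumption, not a theorem, and the package treats that
simulation as a diagnostic.

# Meta-analysis

City coefficients are pooled by DerSimonian–Laird as the default
random-effects estimator — the classic choice in this literature — with
Cochran's $Q$, $I^2$ and a moment $\tau^2$; `method = "reml"` replaces the
moment step with restricted maximum likelihood (1-D optimization of the
profiled restricted likelihood). The estimator choice is exposed because
the convention in published multi-city studies is rarely explicit.

## Pooling curves

Each city's exposure–response curve is a quadratic B-spline of the lagged
exposure with one interior knot at the city's 50th percentile (sensitivity
layouts: 25/50/75 and 10/50/90), centered so the log relative risk is
exactly zero at the city's reference (its minimum observed exposure by
default). The spline replaces the linear exposure term in the stage-1
fit; its coefficients and dispersion-scaled covariance define the curve.

City bases differ (knots and boundaries are city-specific), so before
pooling, each curve is evaluated on a dense grid within its own range and
least-squares-projected onto a *common* 3-dimensional basis — knot at the
pooled (all-city, day-weighted) 50th percentile, boundaries at the pooled
range. An intercept is included in the projection and discarded, since
curves are defined only up to the additive constant fixed by the
reference. The projection operator propagates each covariance. A
common-basis direction with no support inside a city's range is
unidentified for that city; it receives a zero coefficient and a large
(sd 10 on the log-RR scale) variance, so pooling treats the city as
uninformative about it rather than falsely certain. Pooling on the
3-coefficient basis rather than on long prediction vectors keeps the
between-city covariance estimable with ten cities; pooling gridded
predictions directly would require a $\Psi$ far larger than $k$ supports.

The multivariate model is intercept-only random-effects,
$y_i \sim N(\mu, S_i + \Psi)$, with $\Psi$ estimated by REML over its
Cholesky parameterization (BFGS; relative log-likelihood change below
$10^{-9}$, at most 200 iterations; $\Psi \succeq 0$ by construction) and
$\mu$ by generalized least squares at $\hat\Psi$. The pooled covariance is
$\{\sum_i (S_i+\hat\Psi)^{-1}\}^{-1}$. In dimension 1 this reproduces
univariate REML to optimizer precision — a cross-check in the tests. The
integrated curve re-centers the pooled coefficients at the chosen
reference (the observed minimum by default, since a guideline value below
every observed concentration is not estimable from the data; 15 µg/m³ is
available as an option when the data reach it).

# Attributable burden

For each day, $RR_t = \exp\{\mathrm{logRR}(x_t) - \mathrm{logRR}(x_{ref})\}$
from the integrated curve, and the attributable deaths are
$AD_t = Y_t (RR_t - 1)/RR_t$. Conventions, each a deliberate choice:

- $RR_t$ is floored at 1 and days at or below the reference contribute
  zero — the burden is of *excess* exposure above the reference;
- exposures beyond the pooled curve's boundary are evaluated at the
  boundary (flat extrapolation); quadratic extrapolation explodes;
- city AD sums, AF = 100·AD/deaths, and per-year rates use
  follow-up years $n/365.25$. Because cities have unequal follow-up, the
  totals row reports *both* the sum of per-city annual rates and total AD
  over the death-weighted mean follow-up; the two differ and neither is
  canonical.

95% intervals come from `n_sim` (default 1000) multivariate-normal draws
of the pooled coefficients at their estimated covariance, recomputing all
quantities per draw and taking empirical 2.5/97.5 percentiles; a
non-positive-semidefinite covariance is repaired by eigenvalue clipping
and logged. The point estimate always uses the central coefficients, so a
zero covariance collapses the interval onto it exactly.

# The synthetic-data module

`generate_city()` draws from a fully specified data-generating process:

- **Counts.** Negative binomial (NB2) with size $\mu/(\phi-1)$, the
  unique NB parameterization with $\mathrm{Var} = \phi\mu$; quasi-Poisson
  specifies only this mean–variance law, and NB2 is the standard sampling
  law consistent with it. $\phi = 1$ switches to Poisson exactly.
- **Trends.** Annual plus semi-annual mortality harmonics and a slow
  linear drift — smooth structure that a 9 df/year spline should absorb,
  and deliberately simple enough that failures are attributable.
- **Temperature.** Seasonal sinusoid plus AR(1) noise; its mortality
  effect is a softplus-smoothed V around a minimum-mortality temperature,
  smooth enough for a 4-df natural spline to capture.
- **PM2.5.** Lognormal with target mean and SD, whose log-scale variance
  is split between a local component (a smooth monotone function of the
  standardized instruments: decreasing in PBLH and wind, increasing in
  the pressure anomaly), an AR(1) regional transport component, and white
  noise, in proportions set by `local_fraction` and `regional_share`;
  floored at 1 µg/m³. The within-city autocorrelation of transported
  PM2.5 is exposed as a free parameter rather than asserted, since it is
  not characterized in the literature the package follows.
- **Confounding.** A latent standardized AR(1) series $U$ adds
  `confounder_pm` µg/m³ per unit to PM2.5 and `confounder_mort` to log
  mortality. With AR(1) persistence of a few days, $U$ is fast enough
  that the seasonal spline cannot remove it — precisely the regime the IV
  stage exists for.
- **Truth.** The true exposure–response (linear slope, or the supralinear
  form $\alpha\{1-e^{-x/s}\}$ whose local slope decays in $x$) acts on
  the 2-day moving average and is stored with the series.

The default ten-city set reproduces the observed spread of Indian urban
PM2.5 climates (long-term city means from about 28 to 113 µg/m³, with
proportionally larger day-to-day spread in the most polluted cities),
daily death counts from under ten to several hundred, 3–7 years of
follow-up per city, overdispersion 1.3, and a shared supralinear curve
with per-city steepness multipliers between 0.7 and 1.3 to induce
realistic between-city heterogeneity.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: within-city spatial exposure
misclassification, registry under-reporting, influenza epidemics or heat
waves beyond the smooth temperature term, holiday effects, multi-day
distributed lags, and co-pollutants. Its purpose is calibration of the
estimators under a known truth, not realism for its own sake.

# Test and simulation sizes

The package's property checks use sizes chosen to make each property
measurable with modest Monte-Carlo error: 200 replicates of a 5-year,
200-deaths/day city for coefficient recovery and interval coverage; 100
replicates of a confounded 3-year city for the IV de-confounding
comparison; 20 replicate 50-city panels for the between-city covariance
recovery (a single 50-city panel estimates covariance entries with about
20% relative sampling error, so the bias check is run on the mean across
panels); a six-city 3-year world for curve-shape recovery; and 100
four-city 2-year worlds at 500 draws each for attributable-fraction
coverage. The end-to-end default world uses the full ten cities with
their unequal follow-up.

# Known limitations

- The df-targeted smoothing treats the seasonal spline's df as fixed
  rather than estimated; uncertainty in $\lambda$ is not propagated
  (standard in this design, but worth stating).
- The IV standard error is the plug-in quasi-Poisson one; no formal
  two-stage correction for first-stage estimation noise is applied,
  matching the procedure the estimator mirrors.
- In-sample instrument fitting leaves a residual confounding leak
  (reduced by `cross_fit`), and the exclusion restriction is untestable.
- The integrated curve extrapolates flat beyond the pooled exposure
  range; attributable burden at exposures far outside it is not
  meaningful.
- REML for $\Psi$ with ten cities and three dimensions is near the
  practical identifiability boundary; the convergence flag and $\Psi$
  eigenvalues should be inspected on new data.
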
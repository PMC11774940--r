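# airmort

Multi-city time-series analysis of short-term PM2.5 exposure and daily
all-cause mortality, for environmental epidemiologists studying acute
air-pollution effects in highly polluted settings (the design of the
ten-city Indian analyses). The package chains four estimators:

1. **City-specific quasi-Poisson regression.** For daily deaths
   `Y_t` and the 2-day moving average `x_t` of city PM2.5,

   `log E(Y_t) = α + s(t) + DOW_t + f(temp_t) + β x_t`, `Var(Y_t) = φ E(Y_t)`,

   with `s(t)` a penalised cubic B-spline of calendar day whose smoothing
   parameter is solved so its effective df equals 9 per year, day-of-week
   indicators, and a 4-df natural spline of lag 0–4 temperature. Effects
   are reported as `100·(exp(10β) − 1)` percent per 10 µg/m³.
2. **Instrumental-variable estimator for locally generated pollution.**
   Lagged PM2.5 is residualized on the confounder design; the residuals
   are regressed on three standardized meteorological instruments
   (planetary boundary layer height, wind speed, surface pressure) with
   radial-kernel support-vector regression; the calibrated fitted values
   replace the exposure in the same quasi-Poisson regression, giving a
   causal estimate on the PM2.5 scale.
3. **Random-effects meta-analysis.** DerSimonian–Laird (or REML) pooling
   of city slopes with Q/I²/τ², and multivariate REML pooling of
   quadratic B-spline exposure–response coefficients (knot at the pooled
   median, `y_i ~ N(µ, S_i + Ψ)`) into an integrated curve.
4. **Attributable burden.** Daily attributable deaths
   `AD_t = Y_t (RR_t − 1)/RR_t` above a reference concentration (WHO
   guideline 15 µg/m³, Indian standard 60 µg/m³, or the observed
   minimum), with 95% CIs from 1000 Monte-Carlo draws of the pooled
   coefficients.

Because the mortality registries behind such studies are
access-restricted, the package ships a synthetic multi-city generator
with known ground truth (`city_scenario()`, `generate_city()`,
`default_scenarios()`) emulating the exposure, meteorology, confounding
and overdispersed count structure of the real data; every estimator is
validated against it. See `vignettes/airmort-methods.Rmd` for the full
model account.

## Worked example

```r
library(airmort)

scen <- default_scenarios(seed = 11, n_years = 3)[c(1, 4, 6, 9)]  # 4 cities
cfg  <- run_config(scenarios = scen, thresholds = c(125, 60),
                   n_sim = 200, seed = 11)
res  <- run_pipeline(cfg, out_dir = "run1", quiet = TRUE)

res$pooled
#> random-effects pooling (DL) of 4 cities:
#>   pooled beta = 0.0009426 (se 0.000229) per ug/m3; +0.95% (0.50 to 1.40) per 10 ug/m3
#>   tau2 = 1.24e-07, Q = 37.33 on 3 df (p = 3.92e-08), I2 = 92.0%

res$af
#> attributable burden above 13.5 ug/m3:
#>   Ahmedabad  AF 9.4%, AD 16545 (5519/year) [AF 5.4-13.0]
#>   Delhi      AF 16.9%, AD 53697 (17911/year) [AF 13.6-19.7]
#>   Kolkata    AF 11.7%, AD 23139 (7718/year) [AF 8.1-14.9]
#>   Shimla     AF 7.5%, AD 424 (141/year) [AF 3.9-10.6]
#>   TOTAL      AF 13.4%, AD 93805 (31290/year summed, 31290/year weighted) [AF 10.1-16.5]
#>   (95% CIs from 200 Monte-Carlo draws, seed 788)
```

The pooled row is the percent change in daily mortality per 10 µg/m³ of
PM2.5 (lag 0–1) with its heterogeneity statistics; the burden table gives
each city's attributable fraction and attributable deaths above the
reference (here the observed minimum, 13.5 µg/m³), with Monte-Carlo
intervals. `run_pipeline()` also writes `stage1_estimates.csv`,
`iv_estimates.csv`, `threshold_estimates.csv`, `integrated_curve.csv`,
`attributable_burden.csv`, a round-trippable `config.yaml` and a JSON
manifest with seeds and per-stage diagnostics.

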
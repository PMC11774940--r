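test_that("unpenalized fit matches an independent Newton-Raphson GLM oracle", {
  # 500-day instance with a fixed (unpenalized) seasonal basis
  s <- quick_series(seed = 31, n_years = 3)
  s <- s[1:505, ]
  class(s) <- c("city_series", "data.frame")
  cov0 <- cov_spec(time_penalized = FALSE, time_df_per_year = 6)
  d <- build_design(s, cov0)
  f <- fit_quasipoisson(d)
  X <- cbind(d$X, exposure = d$exposure)
  o <- oracle_glm_poisson(X, d$deaths)
  expect_equal(f$beta, unname(o$beta[ncol(X)]), tolerance = 1e-7)
  expect_equal(f$se, unname(o$se[ncol(X)]), tolerance = 1e-7)
  expect_equal(f$dispersion, o$dispersion, tolerance = 1e-7)
  # and the full coefficient vector
  expect_equal(unname(coef(f)), unname(o$beta), tolerance = 1e-7)
})

test_that("penalized seasonal spline hits the requested effective df", {
  s <- quick_series(seed = 32, n_years = 5)
  f <- fit_quasipoisson(build_design(s))
  expect_equal(f$edf_time, 9 * nrow(s) / 365.25, tolerance = 0.5)
  # sensitivity sweep: 6 df/year
  f6 <- fit_quasipoisson(build_design(s, cov_spec(time_df_per_year = 6)))
  expect_equal(f6$edf_time, 6 * nrow(s) / 365.25, tolerance = 0.5)
  expect_gt(f$edf_time, f6$edf_time)
})

test_that("self-consistency: coefficients recovered from the model's own design", {
  s <- quick_series(seed = 33, n_years = 3)
  cov0 <- cov_spec(time_penalized = FALSE)
  d <- build_design(s, cov0)
  X <- cbind(d$X, d$exposure)
  set.seed(99)
  beta0 <- c(log(150), rnorm(ncol(d$X) - 1, 0, 0.03), 0.0015)
  y <- rpois(nrow(X), exp(drop(X %*% beta0)))
  f <- fit_quasipoisson(d, deaths = y)
  expect_true(all(abs(coef(f) - beta0) < 3 * sqrt(diag(vcov(f))) + 1e-8))
  expect_equal(f$dispersion, 1, tolerance = 0.15)
})

test_that("dispersion scaling inflates SEs but leaves point estimates alone", {
  s <- quick_series(seed = 34, n_years = 3)
  d <- build_design(s)
  f <- fit_quasipoisson(d)
  # rebuild the SE at dispersion 1: se / sqrt(phi); beta must be unchanged
  # by any rescaling of phi, which only enters through the covariance
  expect_equal(f$se / sqrt(f$dispersion) * sqrt(4 * f$dispersion),
               2 * f$se)
  # doubling true overdispersion roughly doubles estimated dispersion
  phis <- vapply(1:4, function(i) {
    a <- fit_quasipoisson(build_design(quick_series(seed = 340 + i,
                                                    overdispersion = 1.2)))
    b <- fit_quasipoisson(build_design(quick_series(seed = 340 + i,
                                                    overdispersion = 2.4)))
    b$dispersion / a$dispersion
  }, numeric(1))
  expect_equal(mean(phis), 2.4 / 1.2, tolerance = 0.25)
})

test_that("percent change matches the closed form and is monotone", {
  expect_equal(percent_change(0, 1e-4)$estimate, 0)
  pc <- percent_change(0.001, 2e-4)
  expect_equal(pc$estimate, (exp(0.01) - 1) * 100, tolerance = 1e-12)
  expect_equal(pc$estimate, 1.00502, tolerance = 1e-5)
  # inversion: slope log(1.0142)/10 per ug/m3 -> 1.42% per 10 ug/m3
  expect_equal(percent_change(log(1.0142) / 10, 1e-4)$estimate, 1.42,
               tolerance = 1e-10)
  # strictly increasing in beta, CI brackets the estimate
  b <- seq(-0.002, 0.002, length.out = 11)
  est <- percent_change(b, rep(1e-4, 11))$estimate
  expect_true(all(diff(est) > 0))
  expect_true(all(pc$ci_low <= pc$estimate & pc$estimate <= pc$ci_high))
  # CI symmetric in sign on the log scale around beta = 0
  pc0 <- percent_change(0, 3e-4)
  expect_equal(log1p(pc0$ci_high / 100), -log1p(pc0$ci_low / 100),
               tolerance = 1e-12)
  expect_error(percent_change(0.001, 0), "se")
})

test_that("degenerate inputs are rejected with informative errors", {
  s <- quick_series(seed = 35)
  d <- build_design(s)
  expect_error(fit_quasipoisson(d, deaths = rep(0L, length(d$deaths))),
               "zero")
  bad <- d$deaths
  bad[5] <- -3L
  expect_error(fit_quasipoisson(d, deaths = bad), "nonnegative")
  d2 <- d
  d2$exposure <- rep(50, length(d$exposure))
  expect_error(fit_quasipoisson(d2), "constant")
})

test_that("lag panel runs one labelled fit per lag and is deterministic", {
  s <- quick_series(seed = 36)
  specs <- list(lag_spec("moving_average", 0:1), lag_spec("single_lag", 0),
                lag_spec("single_lag", 2))
  pan <- run_lag_panel(s, lag_specs = specs)
  expect_equal(nrow(pan), 3)
  expect_equal(pan$lag, c("lag 0-1", "lag 0", "lag 2"))
  # single-spec panel equals the direct fit
  direct <- stage1_row(fit_quasipoisson(build_design(s)), "lag 0-1")
  expect_equal(pan[1, ], direct, ignore_attr = TRUE)
  pan2 <- run_lag_panel(s, lag_specs = specs)
  expect_identical(pan, pan2)
})

test_that("effect concentrated at short lags attenuates at distant lags", {
  # truth acts on the 0-1 moving average; a lag-2 exposure is a diluted
  # proxy, so its estimate shrinks toward zero
  ratio <- vapply(1:3, function(i) {
    s <- quick_series(seed = 360 + i, n_years = 4, base_deaths = 300,
                      curve = linear_curve(0.002))
    pan <- run_lag_panel(s, lag_specs = list(lag_spec("moving_average", 0:1),
                                             lag_spec("single_lag", 2)))
    pan$beta[2] / pan$beta[1]
  }, numeric(1))
  expect_lt(mean(ratio), 0.8)
})
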
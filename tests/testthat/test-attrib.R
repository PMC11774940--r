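# a minimal hand-built curve: log-RR = slope * (x - reference) on [0, 500]
toy_curve <- function(slope = log(2) / 50, lo = 0, hi = 500, ref = 0) {
  sp <- resolve_spline_spec(spline_spec(50), seq(lo, hi, length.out = 101))
  B <- erc_basis(seq(lo, hi, length.out = 101), sp, ref)
  coeffs <- drop(qr.solve(B, slope * (seq(lo, hi, length.out = 101) - ref)))
  structure(list(coeffs = coeffs, vcov = diag(0, 3), spec = sp,
                 reference = ref, range = c(lo, hi), city_id = NULL),
            class = "erc_curve")
}

test_that("daily attributable deaths match closed forms", {
  cu <- toy_curve()  # RR doubles every 50 ug/m3 above 0
  # exposure at reference -> 0
  expect_equal(daily_attributable(100, 10, cu, 10), 0)
  # deaths 100 at RR 2 -> 50
  expect_equal(daily_attributable(100, 50, cu, 0), 50, tolerance = 1e-6)
  # below reference -> 0 (RR floored)
  expect_equal(daily_attributable(100, 5, cu, 10), 0)
  expect_error(daily_attributable(-1, 50, cu, 0), "nonnegative")
})

test_that("three-day toy series matches the hand-computed oracle", {
  # RR 1.0, 1.1, 1.2 with deaths 10, 20, 30:
  # AD = 0 + 20*(0.1/1.1) + 30*(0.2/1.2) = 6.8181...
  slope <- log(1.1) / 10  # RR 1.1 at x=10, 1.21 at 20 -- need exact RRs, so
  # build exposures giving the exact RRs under the toy slope
  cu <- toy_curve(slope = 1, lo = 0, hi = 2, ref = 0)  # logRR = x
  x <- log(c(1.0, 1.1, 1.2))
  ad <- daily_attributable(c(10, 20, 30), x, cu, 0)
  expect_equal(sum(ad), 20 * (0.1 / 1.1) + 30 * (0.2 / 1.2), tolerance = 1e-6)
  expect_equal(sum(ad), 6.818182, tolerance = 1e-5)
})

test_that("vectorized totals equal the brute-force daily loop to 10 digits", {
  set.seed(81)
  s <- quick_series(seed = 81, n_years = 3)
  cu <- fit_city_curve(s)
  ref <- cu$reference + 5
  af <- total_af(s, cu, ref)
  ev <- lagged(s$pm25, lag_spec("moving_average", 0:1))
  ok <- !is.na(ev)
  loop_total <- oracle_af_loop(s$deaths[ok], ev[ok], cu, ref)
  expect_equal(af$per_city$attributable_deaths, loop_total, tolerance = 1e-10)
})

test_that("attribution identities: null curve, constant RR, totals row", {
  s1 <- quick_series(seed = 82, n_years = 2)
  s2 <- generate_city(quick_scenario(seed = 83, n_years = 2,
                                     base_deaths = 80))
  flat <- toy_curve(slope = 0)
  af0 <- total_af(list(s1, s2), flat, 10)
  expect_equal(af0$totals$attributable_deaths, 0)
  expect_equal(af0$per_city$af_percent, c(0, 0))
  # constant RR r on all days: AF = 100 (r-1)/r exactly
  cu <- toy_curve(slope = 1, lo = 0, hi = 2, ref = 0)
  s3 <- s1
  s3$pm25 <- rep(log(1.5), nrow(s3))  # logRR = log 1.5 everywhere
  class(s3) <- class(s1)
  af_c <- total_af(s3, cu, 0)
  expect_equal(af_c$per_city$af_percent, 100 * 0.5 / 1.5, tolerance = 1e-10)
  # totals are exact column sums
  cu2 <- toy_curve()
  af2 <- total_af(list(s1, s2), cu2, 20)
  expect_equal(af2$totals$attributable_deaths,
               sum(af2$per_city$attributable_deaths), tolerance = 1e-12)
  expect_equal(af2$totals$total_deaths, sum(af2$per_city$total_deaths))
  # AD < total deaths; AF in [0, 100)
  expect_true(all(af2$per_city$attributable_deaths <
                  af2$per_city$total_deaths))
  expect_true(all(af2$per_city$af_percent >= 0 &
                  af2$per_city$af_percent < 100))
})

test_that("AF is monotone non-decreasing as the reference drops", {
  s <- quick_series(seed = 84, n_years = 2)
  cu <- fit_city_curve(s)
  refs <- quantile(lagged(s$pm25, lag_spec("moving_average", 0:1)),
                   c(0.6, 0.4, 0.2, 0.05), na.rm = TRUE)
  afs <- vapply(refs, function(r) total_af(s, cu, r)$totals$af_percent,
                numeric(1))
  expect_true(all(diff(afs) >= -1e-12))
})

test_that("Monte-Carlo intervals behave: collapse at zero variance, stable", {
  scen <- default_scenarios(seed = 85, n_years = 2)[c(1, 4, 9)]
  series <- generate_multicity(scen)
  curves <- lapply(series, fit_city_curve)
  all_exp <- unlist(lapply(series, function(s)
    lagged(s$pm25, lag_spec("moving_average", 0:1))))
  all_exp <- all_exp[!is.na(all_exp)]
  common <- resolve_spline_spec(spline_spec(50), all_exp)
  ref <- min(all_exp)
  mv <- mvmeta_pool(project_to_common_basis(curves, common, ref))

  mv0 <- mv
  mv0$vcov_mu <- matrix(0, 3, 3)
  af0 <- monte_carlo_ci(series, mv0, common, ref, n_sim = 200, seed = 1)
  expect_equal(af0$ci$totals$af_low, af0$totals$af_percent, tolerance = 1e-9)
  expect_equal(af0$ci$totals$af_high, af0$totals$af_percent, tolerance = 1e-9)

  af1 <- monte_carlo_ci(series, mv, common, ref, n_sim = 400, seed = 2)
  af2 <- monte_carlo_ci(series, mv, common, ref, n_sim = 800, seed = 2)
  # point estimates identical; bounds stable under more draws
  expect_equal(af1$totals$af_percent, af2$totals$af_percent)
  expect_equal(af1$ci$totals$af_low, af2$ci$totals$af_low,
               tolerance = 0.05 * af1$totals$af_percent)
  expect_equal(af1$ci$totals$af_high, af2$ci$totals$af_high,
               tolerance = 0.05 * af1$totals$af_percent)
  # CI brackets the point estimate; same seed reproduces exactly
  expect_lte(af1$ci$totals$af_low, af1$totals$af_percent)
  expect_gte(af1$ci$totals$af_high, af1$totals$af_percent)
  af1b <- monte_carlo_ci(series, mv, common, ref, n_sim = 400, seed = 2)
  expect_identical(af1$ci, af1b$ci)
  expect_warning(monte_carlo_ci(series, mv, common, ref, n_sim = 50, seed = 3),
                 "n_sim")
})

test_that("burden export table mirrors the per-city + totals structure", {
  scen <- default_scenarios(seed = 86, n_years = 2)[c(1, 9)]
  series <- generate_multicity(scen)
  cu <- toy_curve(slope = 0.002, lo = 0, hi = 300)
  af <- total_af(series, cu, 15)
  tab <- af_table(af, series)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$city[3], "Total")
  expect_equal(tab$attributable_deaths[3], sum(tab$attributable_deaths[1:2]))
  expect_equal(tab$pm_mean[1], mean(series[[1]]$pm25))
})
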
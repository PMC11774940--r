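test_that("spline spec validates and resolves knots at exposure quantiles", {
  expect_error(spline_spec(c(0, 50)), "knot_percentiles|>")
  expect_error(spline_spec(c(75, 25)))
  sp <- resolve_spline_spec(spline_spec(50), seq(10, 100, length.out = 1000))
  expect_equal(sp$knots, 55, tolerance = 0.1)
  expect_equal(sp$boundary, c(10, 100))
  sp3 <- resolve_spline_spec(spline_spec(c(25, 50, 75)), seq(0, 100, 0.1))
  expect_equal(sp3$knots, c(25, 50, 75), tolerance = 0.1)
})

test_that("curve prediction is exactly zero at the reference", {
  s <- quick_series(seed = 71)
  cu <- fit_city_curve(s)
  expect_equal(predict(cu, cu$reference)$log_rr, 0)
  expect_equal(predict(cu, cu$reference)$rr, 1)
  # reference defaults to the city's minimum lagged exposure
  ev <- lagged(s$pm25, lag_spec("moving_average", 0:1))
  expect_equal(cu$reference, min(ev, na.rm = TRUE))
})

test_that("a linear truth yields a curve close to the linear fit", {
  s <- quick_series(seed = 72, n_years = 4, base_deaths = 300)
  cu <- fit_city_curve(s)
  lin <- fit_quasipoisson(build_design(s))
  grid <- cu$grid
  pr <- predict(cu, grid)
  lin_pred <- lin$beta * (grid - cu$reference)
  expect_true(all(abs(pr$log_rr - lin_pred) < 2 * pr$se + 1e-8))
})

test_that("re-centering shifts log-RR by a constant; RR ratios invariant", {
  s <- quick_series(seed = 73)
  cu <- fit_city_curve(s)
  x <- c(30, 60, 90)
  p1 <- predict(cu, x)
  cu2 <- recenter_curve(cu, 50)
  p2 <- predict(cu2, x)
  expect_equal(predict(cu2, 50)$log_rr, 0)
  shift <- p1$log_rr - p2$log_rr
  expect_equal(diff(shift), c(0, 0), tolerance = 1e-12)
  expect_equal(p1$log_rr[3] - p1$log_rr[1], p2$log_rr[3] - p2$log_rr[1],
               tolerance = 1e-12)
})

test_that("projection onto the same basis is the identity", {
  s <- quick_series(seed = 74)
  cu <- fit_city_curve(s)
  pr <- project_to_common_basis(list(cu), cu$spec, cu$reference)[[1]]
  expect_equal(pr$coeffs, unname(cu$coeffs), tolerance = 1e-10)
  expect_equal(pr$vcov, unname(cu$vcov), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("projection reproduces smooth curves: nesting and round-trip", {
  s <- quick_series(seed = 75)
  cu <- fit_city_curve(s)
  # common basis with different knot: projection must still reproduce the
  # original quadratic-spline predictions where knots differ only mildly?
  # exact nesting case: a straight line lies in every quadratic basis
  sp <- resolve_spline_spec(spline_spec(50), cu$grid)
  slope <- 0.0012
  line_curve <- structure(list(
    coeffs = drop(MASS::ginv(erc_basis(cu$grid, cu$spec, cu$reference)) %*%
                    (slope * (cu$grid - cu$reference))),
    vcov = diag(1e-8, 3), spec = cu$spec, reference = cu$reference,
    range = cu$range, city_id = "line"), class = "erc_curve")
  pr <- project_to_common_basis(list(line_curve), sp, 30)[[1]]
  proj_curve <- structure(list(coeffs = pr$coeffs, vcov = pr$vcov, spec = sp,
                               reference = 30, range = sp$boundary,
                               city_id = "proj"), class = "erc_curve")
  grid <- seq(max(cu$range[1], sp$boundary[1]), min(cu$range[2], sp$boundary[2]),
              length.out = 40)
  got <- predict(proj_curve, grid)$log_rr
  want <- slope * (grid - 30)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("non-overlapping city ranges are rejected with the city named", {
  s <- quick_series(seed = 76)
  cu <- fit_city_curve(s)
  far <- resolve_spline_spec(spline_spec(50), seq(5000, 6000))
  expect_error(project_to_common_basis(list(cu), far, 5500), "TestCity")
})

test_that("identical cities pool to themselves with negligible Psi", {
  y <- c(0.05, 0.12, 0.2)
  S <- diag(c(1e-4, 2e-4, 1.5e-4))
  cc <- lapply(1:5, function(i) list(coeffs = y, vcov = S))
  mv <- mvmeta_pool(cc)
  expect_equal(mv$mu, y, tolerance = 1e-6)
  expect_lt(max(abs(mv$Psi)), 1e-5)
})

test_that("dimension-1 multivariate pooling equals univariate REML", {
  set.seed(77)
  k <- 10
  v <- runif(k, 0.25, 4) * 1e-6
  y <- rnorm(k, 0.0015, sqrt(2.5e-7 + v))
  mv <- mvmeta_pool(lapply(seq_len(k), function(i)
    list(coeffs = y[i], vcov = matrix(v[i], 1, 1))))
  un <- pool(y, sqrt(v), method = "reml")
  expect_equal(drop(mv$mu), un$beta_pooled, tolerance = 1e-6)
  expect_equal(drop(mv$Psi), un$tau2, tolerance = 1e-5)
  expect_equal(sqrt(drop(mv$vcov_mu)), un$se_pooled, tolerance = 1e-6)
})

test_that("imposing zero heterogeneity reduces pooling to inverse variance", {
  set.seed(78)
  k <- 6
  cc <- lapply(seq_len(k), function(i)
    list(coeffs = rnorm(2, c(0.1, 0.2), 0.01),
         vcov = diag(runif(2, 1e-4, 4e-4))))
  # fixed-effect GLS by hand
  W <- Reduce(`+`, lapply(cc, function(z) solve(z$vcov)))
  b <- Reduce(`+`, lapply(cc, function(z) solve(z$vcov) %*% z$coeffs))
  mu_fe <- drop(solve(W, b))
  # near-zero Psi start: cities drawn with no heterogeneity, so the REML
  # estimate of Psi collapses and mu approaches the fixed-effect solution
  mv <- mvmeta_pool(cc)
  expect_equal(mv$mu, mu_fe, tolerance = 0.15)
})

test_that("integrated curve has RR exactly 1 at its reference", {
  scen <- default_scenarios(seed = 79, n_years = 2)[c(2, 4, 6, 10)]
  series <- generate_multicity(scen)
  curves <- lapply(series, fit_city_curve)
  all_exp <- unlist(lapply(series, function(s)
    lagged(s$pm25, lag_spec("moving_average", 0:1))))
  all_exp <- all_exp[!is.na(all_exp)]
  common <- resolve_spline_spec(spline_spec(50), all_exp)
  ref <- min(all_exp)
  mv <- mvmeta_pool(project_to_common_basis(curves, common, ref))
  ic <- integrated_curve(mv, common, ref)
  expect_equal(predict(ic, ref)$rr, 1)
  expect_error(integrated_curve(mv, common, -5), "reference")
  # pointwise bands widen toward the sparse upper tail
  pr <- ic$predictions
  upper_band <- pr$se[pr$x > quantile(all_exp, 0.99)]
  mid_band <- pr$se[pr$x > quantile(all_exp, 0.4) & pr$x < quantile(all_exp, 0.6)]
  expect_gt(mean(upper_band), mean(mid_band))
})
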
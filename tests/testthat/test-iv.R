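test_that("exposure residuals are mean-zero and vanish for spanned exposures", {
  s <- quick_series(seed = 41)
  rz <- residualize_exposure(s)
  expect_equal(mean(rz$residuals), 0, tolerance = 1e-10)
  # exposure that is exactly a linear combination of design columns
  d <- build_design(s)
  s2 <- s
  fake <- numeric(nrow(s))
  fake[d$rows] <- drop(d$X %*% rnorm(ncol(d$X), 0, 0.1)) + 50
  fake[-d$rows] <- 50
  s2$pm25 <- fake - min(fake) + 1
  class(s2) <- class(s)
  # single-lag 0 keeps the column structure intact
  rz2 <- residualize_exposure(s2, exposure_lag = lag_spec("single_lag", 0))
  expect_lt(max(abs(rz2$residuals)), 1e-8)
})

# fully local PM2.5 driven mainly by day-to-day boundary-layer variation:
# the cleanest regime for the instrument diagnostics below
pblh_dominant_series <- function(seed) {
  generate_city(city_scenario("T", n_years = 3, base_deaths = 150,
                              local_fraction = 1,
                              pblh = c(650, 0, 300), wind = c(3, 0.3, 0.1),
                              pressure = c(1008, 2, 0.5), seed = seed))
}

test_that("with fully local PM2.5 the residuals track the instruments", {
  s <- pblh_dominant_series(seed = 42)
  rz <- residualize_exposure(s)
  la <- lag_spec("moving_average", 0:1)
  cors <- abs(cor(rz$residuals,
                  cbind(lagged(s$pblh, la), lagged(s$wind, la),
                        lagged(s$pressure, la))[rz$rows, ]))
  expect_gt(max(cors), 0.5)
})

test_that("SVR calibration: null residuals give a null instrument", {
  set.seed(43)
  instr <- matrix(rnorm(900), 300, 3,
                  dimnames = list(NULL, c("pblh", "wind", "pressure")))
  cal <- calibrate_instrument(rep(0, 300), instr, rescale = FALSE)
  expect_lt(max(abs(cal$values)), 0.1)
  # small-amplitude noise residuals stay inside the epsilon tube
  cal2 <- calibrate_instrument(rnorm(300, 0, 1e-6), instr, rescale = FALSE)
  expect_lt(max(abs(cal2$values)), 0.1)
})

test_that("SVR calibration recovers a smooth noiseless instrument signal", {
  set.seed(44)
  pblh <- runif(800, 200, 1500)
  instr <- cbind(pblh = pblh, wind = rnorm(800, 3, 1),
                 pressure = rnorm(800, 1008, 4))
  y <- 40 * exp(-pblh / 500)
  cal <- calibrate_instrument(y - mean(y), instr)
  expect_gt(cal$r_squared, 0.9)
})

test_that("permuting instrument days destroys the calibration", {
  s <- pblh_dominant_series(seed = 45)
  rz <- residualize_exposure(s)
  la <- lag_spec("moving_average", 0:1)
  instr <- cbind(pblh = lagged(s$pblh, la), wind = lagged(s$wind, la),
                 pressure = lagged(s$pressure, la))[rz$rows, ]
  cal <- calibrate_instrument(rz$residuals, instr)
  set.seed(46)
  cal_perm <- calibrate_instrument(rz$residuals, instr[sample(nrow(instr)), ])
  expect_gt(cal$r_squared, 0.25)
  expect_lt(cal_perm$r_squared, 0.1)
  expect_lt(cal_perm$r_squared, cal$r_squared / 3)
})

test_that("degenerate instruments are rejected by name", {
  expect_error(calibrate_instrument(rnorm(100),
                                    cbind(pblh = rep(1, 100),
                                          wind = rnorm(100),
                                          pressure = rnorm(100))),
               "pblh")
})

test_that("the calibrated instrument is orthogonal to the confounder design", {
  s <- generate_city(quick_scenario(seed = 47, n_years = 4, local_fraction = 0.7))
  iv <- iv_effect(s)
  d <- build_design(s)
  cors <- abs(cor(iv$instrument$values, d$X[, -1]))
  expect_lt(max(cors), 0.05)
})

test_that("hyperparameters and calibration line are recorded", {
  s <- quick_series(seed = 48)
  iv <- iv_effect(s, cost = 2, epsilon = 0.05)
  hp <- iv$instrument$hyperparams
  expect_equal(hp$cost, 2)
  expect_equal(hp$epsilon, 0.05)
  expect_equal(hp$gamma, 1 / 3)
  expect_true(hp$rescale)
  expect_true(is.numeric(iv$instrument$scaling$calibration))
})

test_that("without confounding the IV and conventional estimates agree", {
  # joint-CI agreement in a fully-local, unconfounded world
  s <- generate_city(quick_scenario(seed = 49, n_years = 4, base_deaths = 300,
                                    local_fraction = 1))
  naive <- fit_quasipoisson(build_design(s))
  iv <- iv_effect(s)
  joint_se <- sqrt(naive$se^2 + iv$fit$se^2)
  expect_lt(abs(iv$fit$beta - naive$beta), 1.96 * joint_se * 1.5)
})

test_that("cross-fitted instrument variant runs and differs from in-sample", {
  s <- quick_series(seed = 50)
  iv_in <- iv_effect(s)
  iv_cf <- iv_effect(s, cross_fit = 5L)
  expect_false(identical(iv_in$instrument$values, iv_cf$instrument$values))
  expect_equal(iv_cf$instrument$hyperparams$cross_fit, 5L)
})
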
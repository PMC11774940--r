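#' True exposure-response curves for the synthetic generator
#'
#' Ground-truth log relative-risk functions used by [generate_city()]. The
#' linear curve has constant slope `beta` (log-RR per ug/m3). The supralinear
#' curve rises steeply at low concentrations and flattens at high ones:
#' `logRR(x) = alpha * (1 - exp(-x / scale))`, so the local slope
#' `(alpha/scale) * exp(-x/scale)` decreases monotonically in `x`.
#'
#' @param beta slope in log-RR per ug/m3.
#' @param alpha asymptotic log-RR of the supralinear curve (dimensionless).
#' @param scale concentration scale (ug/m3) controlling how fast the
#'   supralinear curve flattens.
#' @return An object of class `true_curve` with a `true_log_rr()` evaluator.
#' @export
linear_curve <- function(beta) {
  stopifnot(is.finite(beta))
  structure(list(kind = "linear", beta = beta), class = "true_curve")
}

#' @rdname linear_curve
#' @export
supralinear_curve <- function(alpha = 0.35, scale = 150) {
  stopifnot(is.finite(alpha), is.finite(scale), scale > 0)
  structure(list(kind = "supralinear", alpha = alpha, scale = scale),
            class = "true_curve")
}

#' Evaluate a ground-truth curve
#'
#' @param curve a `true_curve` object.
#' @param x concentrations (ug/m3).
#' @return log relative risk at `x` (relative to 0).
#' @export
true_log_rr <- function(curve, x) {
  stopifnot(inherits(curve, "true_curve"))
  switch(curve$kind,
    linear = curve$beta * x,
    supralinear = curve$alpha * (1 - exp(-x / curve$scale)),
    stop("unknown curve kind: ", curve$kind)
  )
}

#' @export
print.true_curve <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("linear exposure-response: %.5g log-RR per ug/m3\n", x$beta))
  } else {
    cat(sprintf("supralinear exposure-response: alpha = %.3g, scale = %.3g ug/m3\n",
                x$alpha, x$scale))
  }
  invisible(x)
}

.check_finite <- function(x, name) {
  if (!all(is.finite(unlist(x))))
    stop("non-finite value in scenario field '", name, "'", call. = FALSE)
  invisible(TRUE)
}

#' Define a synthetic city scenario
#'
#' A `city_scenario` fixes every ingredient of one city's data-generating
#' process: expected daily deaths at covariate means, seasonal and long-term
#' trends in mortality, day-of-week effects, a U-shaped temperature-mortality
#' relation, three meteorological instrument series (planetary boundary layer
#' height, wind speed, surface pressure), the composition of PM2.5 (an
#' instrument-driven local component, an autocorrelated regional transport
#' component, white noise and an optional latent confounder), the true
#' exposure-response curve applied to the 2-day moving average, and a
#' quasi-Poisson overdispersion factor.
#'
#' PM2.5 is generated as a lognormal deviate whose log-scale variance is
#' partitioned: a fraction `local_fraction` is carried by a smooth monotone
#' function of the standardized instruments (decreasing in PBLH and wind
#' speed, increasing in the pressure anomaly), and the remainder is split
#' between an AR(1) regional component and white noise. The latent
#' confounder U is a standardized AR(1) series added on the ug/m3 scale
#' (`confounder_pm` per unit U) and on the log-mortality scale
#' (`confounder_mort` per unit U).
#'
#' @param city_id character label, unique within a multi-city set.
#' @param n_years years of daily data (3-12).
#' @param start_date first calendar day (ISO string or Date).
#' @param base_deaths expected daily deaths at covariate means (> 0).
#' @param trend_amplitude log-scale amplitude of the annual mortality harmonic;
#'   a semi-annual harmonic at 40% of this amplitude is added.
#' @param drift_linear log-scale linear drift over the whole period.
#' @param dow_effects 7 log-scale offsets (Mon..Sun); centered internally.
#' @param temp_mean,temp_amplitude,temp_sd mean (deg C), seasonal amplitude
#'   (deg C) and day-to-day AR(1) noise sd (deg C) of daily mean temperature.
#' @param temp_mmt minimum-mortality temperature (deg C).
#' @param temp_cold,temp_heat log-RR slopes per deg C below/above `temp_mmt`
#'   (smoothed V; see [generate_city()]).
#' @param pblh,wind,pressure length-3 numeric vectors `c(mean, amplitude, sd)`
#'   for each instrument (m; m/s; hPa).
#' @param pm_mean,pm_sd target mean and sd of daily PM2.5 (ug/m3).
#' @param local_fraction share of log-scale PM2.5 variance driven by the
#'   instruments (0-1).
#' @param regional_share share of the non-local variance carried by the
#'   AR(1) regional component (the rest is white noise).
#' @param regional_ar lag-1 autocorrelation of the regional component.
#' @param confounder_pm effect of the latent confounder on PM2.5 (ug/m3 per
#'   unit U).
#' @param confounder_mort effect of the latent confounder on log mortality
#'   (per unit U).
#' @param confounder_ar lag-1 autocorrelation of the latent confounder.
#' @param curve a [linear_curve()] or [supralinear_curve()] giving the true
#'   effect of the 2-day moving average of PM2.5 on log mortality.
#' @param overdispersion variance inflation factor phi >= 1 (1 = Poisson).
#' @param humidity optional `c(mean, amplitude, sd)` for relative humidity
#'   (percent); omit for no humidity column.
#' @param seed integer RNG seed; generation is bit-reproducible given seed.
#' @return An object of class `city_scenario`.
#' @export
city_scenario <- function(city_id,
                          n_years = 5,
                          start_date = "2012-01-01",
                          base_deaths = 200,
                          trend_amplitude = 0.12,
                          drift_linear = 0.05,
                          dow_effects = c(0.01, 0, -0.005, 0, 0.005, 0.02, 0.015),
                          temp_mean = 26, temp_amplitude = 6, temp_sd = 1.5,
                          temp_mmt = 27, temp_cold = 0.012, temp_heat = 0.03,
                          pblh = c(650, 250, 140),
                          wind = c(3, 1, 0.8),
                          pressure = c(1008, 6, 3),
                          pm_mean = 60, pm_sd = 25,
                          local_fraction = 0.5,
                          regional_share = 0.6,
                          regional_ar = 0.8,
                          confounder_pm = 0,
                          confounder_mort = 0,
                          confounder_ar = 0.7,
                          curve = linear_curve(0.0014),
                          overdispersion = 1.3,
                          humidity = NULL,
                          seed = 1L) {
  sc <- list(city_id = as.character(city_id), n_years = n_years,
             start_date = as.Date(start_date), base_deaths = base_deaths,
             trend_amplitude = trend_amplitude, drift_linear = drift_linear,
             dow_effects = dow_effects,
             temp_mean = temp_mean, temp_amplitude = temp_amplitude,
             temp_sd = temp_sd, temp_mmt = temp_mmt,
             temp_cold = temp_cold, temp_heat = temp_heat,
             pblh = pblh, wind = wind, pressure = pressure,
             pm_mean = pm_mean, pm_sd = pm_sd,
             local_fraction = local_fraction,
             regional_share = regional_share, regional_ar = regional_ar,
             confounder_pm = confounder_pm, confounder_mort = confounder_mort,
             confounder_ar = confounder_ar,
             curve = curve, overdispersion = overdispersion,
             humidity = humidity, seed = as.integer(seed))
  for (f in setdiff(names(sc), c("city_id", "start_date", "curve", "humidity")))
    .check_finite(sc[[f]], f)
  if (!is.null(humidity)) .check_finite(humidity, "humidity")
  if (!inherits(curve, "true_curve")) stop("curve must be a true_curve object")
  if (length(dow_effects) != 7) stop("dow_effects must have length 7")
  if (local_fraction < 0 || local_fraction > 1)
    stop("local_fraction must lie in [0, 1]")
  if (overdispersion < 1) stop("overdispersion must be >= 1")
  if (base_deaths <= 0) stop("base_deaths must be > 0")
  if (n_years < 1 || n_years > 12) stop("n_years must lie in [1, 12]")
  class(sc) <- "city_scenario"
  sc
}

#' @export
print.city_scenario <- function(x, ...) {
  cat(sprintf("city scenario '%s': %g y, base %.3g deaths/day, PM2.5 %.3g (%.3g) ug/m3\n",
              x$city_id, x$n_years, x$base_deaths, x$pm_mean, x$pm_sd))
  cat(sprintf("  local fraction %.2f, phi %.2f, confounder (%.3g, %.3g), seed %d\n",
              x$local_fraction, x$overdispersion,
              x$confounder_pm, x$confounder_mort, x$seed))
  print(x$curve)
  invisible(x)
}

# standardized AR(1) series (marginal variance 1)
.ar1 <- function(n, rho) {
  if (abs(rho) < 1e-12) return(rnorm(n))
  as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - rho^2)), rho,
                           method = "recursive",
                           init = rnorm(1)))
}

# smoothed V-shaped temperature log-RR: softplus on both sides of the
# minimum-mortality temperature, width k deg C (smooth, so a natural spline
# in the analysis model can absorb it)
.temp_log_rr <- function(temp, mmt, cold, heat, k = 3) {
  cold * k * log1p(exp((mmt - temp) / k)) + heat * k * log1p(exp((temp - mmt) / k))
}

.seasonal <- function(t, amplitude, peak_day, period = 365.25) {
  amplitude * cos(2 * pi * (t - peak_day) / period)
}

# trailing moving average with partial windows at the start (generator-side
# only; the analysis-side lag operator in lagged() drops undefined days)
.ma_partial <- function(x, width) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - width, 0)
  (cs - c(0, cs)[lo + 1]) / (seq_len(n) - lo)
}

#' Generate one city's daily series
#'
#' Draws the full daily series implied by a [city_scenario()]: instruments
#' with seasonal + noise structure, PM2.5 assembled from local (instrument
#' driven), regional AR(1), white-noise and confounder components, and death
#' counts from a negative-binomial law whose mean follows
#' `log E(deaths) = log(base) + season + drift + day-of-week +
#' f(temperature, lag 0-4 mean) + curve(2-day mean PM2.5) + confounder`,
#' with `Var = phi * mean` (NB2 with size `mu / (phi - 1)`; Poisson when
#' `phi = 1`).
#'
#' @param scenario a [city_scenario()].
#' @return A `city_series` data frame with columns `city`, `date`, `deaths`,
#'   `pm25`, `temp`, `pblh`, `wind`, `pressure` (and `humidity` if
#'   configured), carrying a `truth` attribute (scenario, true curve, latent
#'   confounder, true daily means).
#' @export
generate_city <- function(scenario) {
  stopifnot(inherits(scenario, "city_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- round(sc$n_years * 365.25)
  t <- seq_len(n) - 1
  dates <- sc$start_date + t

  # temperature: hot season peaking in late May (day-of-year ~ 140)
  doy0 <- as.numeric(format(sc$start_date, "%j")) - 1
  temp <- sc$temp_mean + .seasonal(t + doy0, sc$temp_amplitude, 140) +
    sc$temp_sd * .ar1(n, 0.6)

  # instruments: deep boundary layer and higher winds in the hot season,
  # higher pressure in winter
  pblh <- sc$pblh[1] + .seasonal(t + doy0, sc$pblh[2], 140) +
    sc$pblh[3] * .ar1(n, 0.4)
  pblh <- pmax(pblh, 50)
  wind <- sc$wind[1] + .seasonal(t + doy0, sc$wind[2], 140) +
    sc$wind[3] * .ar1(n, 0.3)
  wind <- pmax(wind, 0.1)
  pres <- sc$pressure[1] + .seasonal(t + doy0, sc$pressure[2], 0) +
    sc$pressure[3] * .ar1(n, 0.4)

  zs <- function(x) (x - mean(x)) / stats::sd(x)
  # local dispersion index: smooth, monotone decreasing in PBLH and wind,
  # increasing in the pressure anomaly
  local_raw <- exp(-0.5 * zs(pblh) - 0.35 * zs(wind) + 0.25 * zs(pres))
  local_z <- zs(local_raw)
  regional_z <- .ar1(n, sc$regional_ar)
  noise_z <- rnorm(n)
  U <- .ar1(n, sc$confounder_ar)

  fl <- sc$local_fraction
  wr <- sc$regional_share
  z <- sqrt(fl) * local_z + sqrt((1 - fl) * wr) * regional_z +
    sqrt((1 - fl) * (1 - wr)) * noise_z

  # lognormal with target mean/sd on the concentration scale
  s2 <- log1p((sc$pm_sd / sc$pm_mean)^2)
  pm25 <- exp(log(sc$pm_mean) - s2 / 2 + sqrt(s2) * z) + sc$confounder_pm * U
  pm25 <- pmax(pm25, 1)

  pm_ma01 <- .ma_partial(pm25, 2L)
  temp_ma04 <- .ma_partial(temp, 5L)

  season_m <- sc$trend_amplitude * (cos(2 * pi * (t + doy0 - 20) / 365.25) +
                                    0.4 * cos(4 * pi * (t + doy0 - 80) / 365.25)) +
    sc$drift_linear * (t / n - 0.5)
  dow_idx <- (as.integer(format(dates, "%u")))  # 1 = Monday
  dow <- sc$dow_effects - mean(sc$dow_effects)
  f_temp <- .temp_log_rr(temp_ma04, sc$temp_mmt, sc$temp_cold, sc$temp_heat)
  f_pm <- true_log_rr(sc$curve, pm_ma01)

  eta <- log(sc$base_deaths) + season_m + dow[dow_idx] +
    (f_temp - mean(f_temp)) + (f_pm - mean(f_pm)) + sc$confounder_mort * U
  mu <- exp(eta)
  phi <- sc$overdispersion
  deaths <- if (phi <= 1 + 1e-12) rpois(n, mu) else
    rnbinom(n, mu = mu, size = mu / (phi - 1))

  out <- data.frame(city = sc$city_id, date = dates, deaths = deaths,
                    pm25 = pm25, temp = temp, pblh = pblh, wind = wind,
                    pressure = pres, stringsAsFactors = FALSE)
  if (!is.null(sc$humidity)) {
    hum <- sc$humidity[1] + .seasonal(t + doy0, sc$humidity[2], 230) +
      sc$humidity[3] * .ar1(n, 0.5)
    out$humidity <- pmin(pmax(hum, 2), 100)
  }
  attr(out, "truth") <- list(scenario = sc, curve = sc$curve,
                             beta_true = if (sc$curve$kind == "linear") sc$curve$beta else NA_real_,
                             U = U, mu = mu, phi = phi)
  class(out) <- c("city_series", "data.frame")
  out
}

#' Generate a multi-city set of daily series
#'
#' @param scenarios list of [city_scenario()] objects with distinct
#'   `city_id` (at least 2); each scenario carries its own seed so streams
#'   are independent and adding a city does not perturb the others.
#' @return Named list of `city_series`.
#' @export
generate_multicity <- function(scenarios) {
  if (length(scenarios) < 2) stop("need at least 2 scenarios")
  ids <- vapply(scenarios, function(s) s$city_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate city_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(scenarios, generate_city)
  names(out) <- ids
  out
}

#' Default ten-city scenario set
#'
#' Ten cities emulating the observed spread of Indian urban PM2.5 climates:
#' long-term city means from roughly 28 to 113 ug/m3 with proportionally
#' larger day-to-day spread in the most polluted cities, daily death counts
#' from under ten to several hundred, and 3-7 years of follow-up per city.
#' City-to-city heterogeneity in the true effect is introduced through a
#' per-city multiplier on the shared exposure-response curve.
#'
#' @param seed master seed; per-city seeds are derived deterministically.
#' @param n_years optional single value overriding every city's follow-up.
#' @param curve shared true curve; default supralinear.
#' @param curve_scales per-city multipliers on the curve (length 10).
#' @param confounder_pm,confounder_mort latent-confounder strengths applied
#'   to every city (default none).
#' @return List of 10 [city_scenario()] objects.
#' @export
default_scenarios <- function(seed = 20240701L, n_years = NULL,
                              curve = supralinear_curve(alpha = 0.35, scale = 150),
                              curve_scales = c(0.9, 1.3, 1.1, 0.7, 1.0,
                                               1.0, 0.9, 1.1, 1.2, 0.8),
                              confounder_pm = 0, confounder_mort = 0) {
  cities <- data.frame(
    city = c("Ahmedabad", "Bangalore", "Chennai", "Delhi", "Hyderabad",
             "Kolkata", "Mumbai", "Pune", "Shimla", "Varanasi"),
    pm_mean = c(37.9, 33.0, 33.7, 113.0, 38.9, 55.2, 41.7, 45.3, 28.4, 82.1),
    pm_sd   = c(9.7, 6.5, 9.0, 64.5, 10.4, 35.3, 18.5, 22.6, 6.9, 35.3),
    base    = c(160, 120, 160, 290, 55, 180, 250, 65, 5, 45),
    years   = c(6, 4, 7, 7, 4, 7, 5, 4, 5, 3),
    temp    = c(27, 24, 29, 25, 27, 27, 27, 25, 14, 26),
    tamp    = c(5, 3.5, 4, 9, 5, 5, 3.5, 4.5, 8, 9),
    stringsAsFactors = FALSE)
  stopifnot(length(curve_scales) == 10)
  lapply(seq_len(nrow(cities)), function(i) {
    ci <- cities[i, ]
    cv <- if (curve$kind == "linear") linear_curve(curve$beta * curve_scales[i])
          else supralinear_curve(curve$alpha * curve_scales[i], curve$scale)
    city_scenario(
      city_id = ci$city, n_years = if (is.null(n_years)) ci$years else n_years,
      base_deaths = ci$base, pm_mean = ci$pm_mean, pm_sd = ci$pm_sd,
      temp_mean = ci$temp, temp_amplitude = ci$tamp, temp_mmt = ci$temp + 2,
      local_fraction = 0.5, curve = cv, overdispersion = 1.3,
      confounder_pm = confounder_pm, confounder_mort = confounder_mort,
      seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
}

#' Write / read a city series as CSV
#'
#' The on-disk format is one row per day with columns `date` (ISO-8601),
#' `deaths`, `pm25`, `temp`, `pblh`, `wind`, `pressure` and optionally
#' `humidity`. The ground-truth record of a synthetic series, if present,
#' goes to a JSON sidecar (`<path>.truth.json`).
#'
#' @param series a `city_series`.
#' @param path output CSV path.
#' @param truth write the truth sidecar when available.
#' @return `path`, invisibly.
#' @export
write_city_csv <- function(series, path, truth = TRUE) {
  df <- as.data.frame(series)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  tr <- attr(series, "truth")
  if (truth && !is.null(tr)) {
    sc <- tr$scenario
    side <- list(city_id = sc$city_id, seed = sc$seed,
                 curve = tr$curve[setdiff(names(tr$curve), "")],
                 beta_true = tr$beta_true,
                 overdispersion = tr$phi,
                 confounder_pm = sc$confounder_pm,
                 confounder_mort = sc$confounder_mort)
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_city_csv
#' @param city_id label to attach when the CSV has no `city` column.
#' @export
read_city_csv <- function(path, city_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  if (is.null(df$city)) df$city <- if (is.null(city_id))
    sub("\\.csv$", "", basename(path)) else city_id
  stopifnot(!is.unsorted(df$date, strictly = TRUE),
            all(df$deaths >= 0), all(df$pm25 > 0))
  class(df) <- c("city_series", "data.frame")
  df
}
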
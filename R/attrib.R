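#' Daily attributable deaths above a reference concentration
#'
#' For each day, `RR_t = exp(logRR(exposure_t) - logRR(reference))` from the
#' supplied curve; attributable deaths `AD_t = deaths_t * (RR_t - 1)/RR_t`.
#' Days at or below the reference contribute zero, and `RR_t` is floored at
#' 1 (excess risk above the reference cannot be negative under this
#' framing). Exposures beyond the curve's range are evaluated at the
#' boundary.
#'
#' @param deaths daily death counts (nonnegative).
#' @param exposure daily (lagged) exposure, ug/m3.
#' @param curve an `erc_curve`.
#' @param reference reference concentration (ug/m3).
#' @return Vector of daily attributable deaths (>= 0).
#' @export
daily_attributable <- function(deaths, exposure, curve, reference) {
  if (any(deaths < 0)) stop("deaths must be nonnegative")
  stopifnot(length(deaths) == length(exposure))
  B <- erc_basis(exposure, curve$spec, reference)
  rr <- pmax(exp(drop(B %*% curve$coeffs)), 1)
  ad <- deaths * (rr - 1) / rr
  ad[exposure <= reference] <- 0
  ad
}

.af_point <- function(series_list, coeffs, spec, reference, exposure_lag,
                      precomp = NULL) {
  per <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (is.null(precomp)) {
      ev <- lagged(s$pm25, exposure_lag)
      ok <- !is.na(ev)
      B <- erc_basis(ev[ok], spec, reference)
      dth <- s$deaths[ok]
      expo <- ev[ok]
    } else {
      B <- precomp[[i]]$B; dth <- precomp[[i]]$deaths; expo <- precomp[[i]]$exposure
    }
    rr <- pmax(exp(drop(B %*% coeffs)), 1)
    ad <- dth * (rr - 1) / rr
    ad[expo <= reference] <- 0
    c(ad = sum(ad), deaths = sum(dth), n_days = length(dth))
  })
  m <- do.call(rbind, per)
  data.frame(city = vapply(series_list, function(s) s$city[1], character(1)),
             attributable_deaths = m[, "ad"],
             total_deaths = m[, "deaths"],
             af_percent = 100 * m[, "ad"] / m[, "deaths"],
             years = m[, "n_days"] / 365.25,
             attributable_deaths_per_year = m[, "ad"] / (m[, "n_days"] / 365.25),
             stringsAsFactors = FALSE)
}

.af_totals <- function(per_city) {
  ad <- sum(per_city$attributable_deaths)
  dth <- sum(per_city$total_deaths)
  # two aggregation conventions for unequal follow-up, both reported:
  # sum of the per-city annual rates, and total AD over death-weighted
  # mean follow-up
  wyears <- sum(per_city$total_deaths * per_city$years) / sum(per_city$total_deaths)
  data.frame(attributable_deaths = ad, total_deaths = dth,
             af_percent = 100 * ad / dth,
             ad_per_year_sum = sum(per_city$attributable_deaths_per_year),
             ad_per_year_weighted = ad / wyears)
}

#' Attributable fraction and deaths above a reference, point estimates
#'
#' Per city: summed daily attributable deaths, attributable fraction
#' `100 * AD / total deaths`, and AD per follow-up year
#' (`n_days / 365.25`). Totals sum the city values exactly; the total AF is
#' total AD over total deaths. Because cities have unequal follow-up, the
#' totals row carries two per-year conventions: the sum of per-city annual
#' rates (`ad_per_year_sum`) and total AD divided by the death-weighted mean
#' follow-up (`ad_per_year_weighted`).
#'
#' @param series_list list of `city_series`.
#' @param curve an `erc_curve` (typically the integrated curve).
#' @param reference reference concentration, ug/m3 (e.g. the 24-h guideline
#'   value 15, the Indian standard 60, or the observed minimum).
#' @param exposure_lag [lag_spec()] forming the daily exposure metric.
#' @return An `af_result`: `per_city` data frame, `totals`, `reference`.
#' @export
total_af <- function(series_list, curve, reference,
                     exposure_lag = lag_spec("moving_average", 0:1)) {
  if (length(series_list) == 0) stop("empty series list")
  if (inherits(series_list, "city_series")) series_list <- list(series_list)
  per <- .af_point(series_list, curve$coeffs, curve$spec, reference, exposure_lag)
  structure(list(per_city = per, totals = .af_totals(per),
                 reference = reference, curve = curve),
            class = "af_result")
}

#' Monte-Carlo confidence intervals for attributable quantities
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' pooled curve coefficients with the pooled covariance, recomputes every
#' attributable quantity per draw, and reports empirical 2.5th/97.5th
#' percentiles. Point estimates use the central coefficients. A
#' non-positive-semidefinite covariance is repaired by clipping negative
#' eigenvalues at zero (logged via a warning).
#'
#' @param series_list list of `city_series`.
#' @param mvmeta an [mvmeta_pool()] fit (or any `erc_curve` whose `vcov` is
#'   used, via `curve =`).
#' @param common resolved common [spline_spec()].
#' @param reference reference concentration (ug/m3).
#' @param n_sim Monte-Carlo draws (default 1000; < 100 triggers a warning).
#' @param seed integer seed for the draws.
#' @param exposure_lag [lag_spec()].
#' @return An `af_result` with `ci` (per-city and total bounds) attached.
#' @export
monte_carlo_ci <- function(series_list, mvmeta, common, reference,
                           n_sim = 1000L, seed = 1L,
                           exposure_lag = lag_spec("moving_average", 0:1)) {
  if (length(series_list) == 0) stop("empty series list")
  if (inherits(series_list, "city_series")) series_list <- list(series_list)
  if (n_sim < 100) warning("n_sim < 100: Monte-Carlo intervals will be unstable")
  mu <- mvmeta$mu
  V <- (mvmeta$vcov_mu + t(mvmeta$vcov_mu)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values)))) {
    warning("pooled covariance not PSD; repaired by eigenvalue clipping")
    V <- ev$vectors %*% diag(pmax(ev$values, 0), length(mu)) %*% t(ev$vectors)
  }

  precomp <- lapply(series_list, function(s) {
    ev2 <- lagged(s$pm25, exposure_lag)
    ok <- !is.na(ev2)
    list(B = erc_basis(ev2[ok], common, reference),
         deaths = s$deaths[ok], exposure = ev2[ok])
  })

  point_per <- .af_point(series_list, mu, common, reference, exposure_lag,
                         precomp = precomp)
  point_tot <- .af_totals(point_per)

  set.seed(seed)
  draws <- MASS::mvrnorm(n_sim, mu, V)
  k <- length(series_list)
  ad_sims <- matrix(0, n_sim, k)
  for (i in seq_len(k)) {
    pc <- precomp[[i]]
    lrr <- pc$B %*% t(draws)               # n_days x n_sim
    rr <- exp(lrr)
    rr[rr < 1] <- 1
    frac <- (rr - 1) / rr
    frac[pc$exposure <= reference, ] <- 0
    ad_sims[, i] <- colSums(frac * pc$deaths)
  }
  tot_deaths <- point_per$total_deaths
  af_sims <- sweep(ad_sims, 2, tot_deaths, "/") * 100
  adyr_sims <- sweep(ad_sims, 2, point_per$years, "/")
  tot_ad <- rowSums(ad_sims)
  tot_af <- 100 * tot_ad / sum(tot_deaths)

  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  ci_per <- data.frame(
    city = point_per$city,
    ad_low = apply(ad_sims, 2, function(v) qs(v)[1]),
    ad_high = apply(ad_sims, 2, function(v) qs(v)[2]),
    af_low = apply(af_sims, 2, function(v) qs(v)[1]),
    af_high = apply(af_sims, 2, function(v) qs(v)[2]),
    ad_per_year_low = apply(adyr_sims, 2, function(v) qs(v)[1]),
    ad_per_year_high = apply(adyr_sims, 2, function(v) qs(v)[2]),
    stringsAsFactors = FALSE)
  wyears <- point_tot$attributable_deaths / point_tot$ad_per_year_weighted
  ci_tot <- data.frame(
    ad_low = qs(tot_ad)[1], ad_high = qs(tot_ad)[2],
    af_low = qs(tot_af)[1], af_high = qs(tot_af)[2],
    ad_per_year_sum_low = qs(rowSums(adyr_sims))[1],
    ad_per_year_sum_high = qs(rowSums(adyr_sims))[2],
    ad_per_year_weighted_low = qs(tot_ad / wyears)[1],
    ad_per_year_weighted_high = qs(tot_ad / wyears)[2])

  structure(list(per_city = point_per, totals = point_tot,
                 ci = list(per_city = ci_per, totals = ci_tot),
                 reference = reference, n_sim = n_sim, seed = seed),
            class = "af_result")
}

#' @export
print.af_result <- function(x, ...) {
  cat(sprintf("attributable burden above %.1f ug/m3:\n", x$reference))
  per <- x$per_city
  for (i in seq_len(nrow(per))) {
    ln <- sprintf("  %-10s AF %.1f%%, AD %.0f (%.0f/year)",
                  per$city[i], per$af_percent[i], per$attributable_deaths[i],
                  per$attributable_deaths_per_year[i])
    if (!is.null(x$ci))
      ln <- paste0(ln, sprintf(" [AF %.1f-%.1f]", x$ci$per_city$af_low[i],
                               x$ci$per_city$af_high[i]))
    cat(ln, "\n")
  }
  tt <- x$totals
  ln <- sprintf("  TOTAL      AF %.1f%%, AD %.0f (%.0f/year summed, %.0f/year weighted)",
                tt$af_percent, tt$attributable_deaths,
                tt$ad_per_year_sum, tt$ad_per_year_weighted)
  if (!is.null(x$ci))
    ln <- paste0(ln, sprintf(" [AF %.1f-%.1f]", x$ci$totals$af_low,
                             x$ci$totals$af_high))
  cat(ln, "\n")
  if (!is.null(x$n_sim))
    cat(sprintf("  (95%% CIs from %d Monte-Carlo draws, seed %d)\n",
                x$n_sim, x$seed))
  invisible(x)
}

#' Attributable-burden export table
#'
#' One row per city plus a totals row, mirroring the structure of published
#' burden tables: mean (SD) exposure, AF (CI), AD (CI), AD/year (CI).
#'
#' @param af an `af_result` (with Monte-Carlo CIs for the CI columns).
#' @param series_list the series used, for the exposure summary columns.
#' @return Data frame.
#' @export
af_table <- function(af, series_list) {
  if (inherits(series_list, "city_series")) series_list <- list(series_list)
  pm_mean <- vapply(series_list, function(s) mean(s$pm25), numeric(1))
  pm_sd <- vapply(series_list, function(s) stats::sd(s$pm25), numeric(1))
  per <- af$per_city
  out <- data.frame(city = per$city, pm_mean = pm_mean, pm_sd = pm_sd,
                    af_percent = per$af_percent,
                    attributable_deaths = per$attributable_deaths,
                    ad_per_year = per$attributable_deaths_per_year,
                    stringsAsFactors = FALSE)
  if (!is.null(af$ci)) {
    out$af_low <- af$ci$per_city$af_low; out$af_high <- af$ci$per_city$af_high
    out$ad_low <- af$ci$per_city$ad_low; out$ad_high <- af$ci$per_city$ad_high
  }
  all_pm <- unlist(lapply(series_list, function(s) s$pm25))
  tot <- data.frame(city = "Total", pm_mean = mean(all_pm), pm_sd = stats::sd(all_pm),
                    af_percent = af$totals$af_percent,
                    attributable_deaths = af$totals$attributable_deaths,
                    ad_per_year = af$totals$ad_per_year_weighted,
                    stringsAsFactors = FALSE)
  if (!is.null(af$ci)) {
    tot$af_low <- af$ci$totals$af_low; tot$af_high <- af$ci$totals$af_high
    tot$ad_low <- af$ci$totals$ad_low; tot$ad_high <- af$ci$totals$ad_high
  }
  rbind(out, tot)
}
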
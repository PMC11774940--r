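#' Lag specification
#'
#' Describes how a daily series is lagged before entering the regression:
#' either a single lag (`single_lag`, one offset) or the mean over a set of
#' day offsets (`moving_average`; offsets 0:1 give the 2-day moving average
#' of the current and previous day, the main exposure metric).
#'
#' @param kind `"moving_average"` or `"single_lag"`.
#' @param lags nonnegative integer day offsets, sorted.
#' @return A `lag_spec` object.
#' @export
lag_spec <- function(kind = c("moving_average", "single_lag"), lags = 0:1) {
  kind <- match.arg(kind)
  lags <- as.integer(lags)
  if (any(lags < 0)) stop("lags must be nonnegative")
  if (is.unsorted(lags)) stop("lags must be sorted")
  if (kind == "single_lag" && length(lags) != 1)
    stop("single_lag takes exactly one offset")
  structure(list(kind = kind, lags = lags), class = "lag_spec")
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("%s lag %s\n", x$kind,
              if (length(x$lags) > 1) paste0(min(x$lags), "-", max(x$lags))
              else x$lags))
  invisible(x)
}

#' @export
format.lag_spec <- function(x, ...) {
  if (x$kind == "moving_average" && length(x$lags) > 1)
    sprintf("lag %d-%d", min(x$lags), max(x$lags))
  else sprintf("lag %d", x$lags[1])
}

#' Apply a lag specification to a daily vector
#'
#' The first `max(lags)` entries are undefined (`NA`) and are dropped later
#' when the design is assembled.
#'
#' @param values daily vector.
#' @param spec a [lag_spec()].
#' @return Vector of the same length with leading `NA`s.
#' @export
lagged <- function(values, spec) {
  stopifnot(inherits(spec, "lag_spec"))
  n <- length(values)
  mx <- max(spec$lags)
  if (mx >= n) stop("maximum lag (", mx, ") must be smaller than series length")
  shift1 <- function(l) c(rep(NA_real_, l), values[seq_len(n - l)])
  out <- if (spec$kind == "single_lag") shift1(spec$lags) else
    rowMeans(vapply(spec$lags, shift1, numeric(n)))
  if (mx > 0) out[seq_len(mx)] <- NA_real_
  out
}

#' Covariate specification for the mortality regressions
#'
#' Fixes the confounder adjustment shared by the conventional and the
#' instrumental-variable regressions: a penalised cubic B-spline of calendar
#' day targeted at `time_df_per_year` effective degrees of freedom per year,
#' day-of-week indicators, and a natural cubic spline of lagged daily mean
#' temperature with `temp_df` df (interior knots at equally spaced quantiles,
#' boundary knots at the observed min/max). Optional humidity adjustment.
#'
#' @param time_df_per_year target effective df per year for the seasonal
#'   spline (default 9; sensitivity range 6-10).
#' @param temp_lag [lag_spec()] for temperature (default moving average 0-4).
#' @param temp_df df of the temperature spline (default 4).
#' @param dow include day-of-week indicators (reference Monday).
#' @param humidity optional `list(lag = lag_spec(...), df = integer)`.
#' @param time_penalized if `FALSE` the seasonal term is an unpenalised
#'   natural spline with exactly `round(time_df_per_year * years)` df
#'   (useful for oracle comparisons against plain GLM fits).
#' @param basis_margin extra B-spline basis columns beyond the df target that
#'   the penalty shrinks away (ignored when `time_penalized = FALSE`).
#' @return A `cov_spec` object.
#' @export
cov_spec <- function(time_df_per_year = 9,
                     temp_lag = lag_spec("moving_average", 0:4),
                     temp_df = 4,
                     dow = TRUE,
                     humidity = NULL,
                     time_penalized = TRUE,
                     basis_margin = 10L) {
  if (time_df_per_year < 2 || temp_df < 2) stop("df values must be >= 2")
  if (!is.null(humidity))
    stopifnot(inherits(humidity$lag, "lag_spec"), humidity$df >= 2)
  structure(list(time_df_per_year = time_df_per_year, temp_lag = temp_lag,
                 temp_df = temp_df, dow = dow, humidity = humidity,
                 time_penalized = isTRUE(time_penalized),
                 basis_margin = as.integer(basis_margin)),
            class = "cov_spec")
}

# second-difference penalty for K B-spline coefficients, reparameterized by Z
.diff_penalty <- function(K) {
  D <- diff(diag(K), differences = 2)
  crossprod(D)
}

# sum-to-zero constrained cubic B-spline basis over x (numeric), K columns
# before constraint; returns list(B, S) with K-1 columns
.time_basis <- function(x, K) {
  rng <- range(x)
  B <- splines::bs(x, df = K, degree = 3, intercept = TRUE,
                   Boundary.knots = rng)
  S <- .diff_penalty(ncol(B))
  # absorb the sum-to-zero (column-mean) constraint so the basis is
  # identifiable next to an intercept
  C <- matrix(colMeans(B), nrow = 1)
  Z <- qr.Q(qr(t(C)), complete = TRUE)[, -1, drop = FALSE]
  list(B = unclass(B) %*% Z, S = t(Z) %*% S %*% Z)
}

#' Build the regression design for one city
#'
#' Assembles analysis rows (days with all lags defined, optionally further
#' restricted), the confounder matrix (intercept, seasonal spline basis,
#' day-of-week indicators, temperature spline, optional humidity spline),
#' the block penalty acting on the seasonal spline coefficients only, and
#' the lagged exposure kept separate from the confounder block.
#'
#' @param series a `city_series` (or a subset from [restrict_below()]).
#' @param cov a [cov_spec()].
#' @param exposure_lag [lag_spec()] for PM2.5 (default 2-day moving average).
#' @param exposure optional replacement daily exposure vector on the full
#'   series (e.g. a calibrated instrument already on analysis days: then pass
#'   via `exposure_analysis`).
#' @param exposure_analysis optional exposure already aligned to analysis
#'   days (overrides `exposure`/`exposure_lag`; used by the IV stage).
#' @return A `mortality_design`: list with elements `X` (confounders),
#'   `exposure`, `S` (penalty for the time block), `blocks` (column index
#'   sets), `deaths`, `dates`, `rows`, `target_edf`, `penalized`.
#' @export
build_design <- function(series, cov = cov_spec(),
                         exposure_lag = lag_spec("moving_average", 0:1),
                         exposure = NULL, exposure_analysis = NULL) {
  keep_extra <- NULL
  if (inherits(series, "restricted_series")) {
    keep_extra <- series$keep
    if (!is.null(series$exposure_lag)) exposure_lag <- series$exposure_lag
    series <- series$series
  }
  stopifnot(inherits(series, "city_series"))
  n <- nrow(series)
  years <- n / 365.25

  xvals <- if (is.null(exposure)) series$pm25 else exposure
  exp_lagged <- lagged(xvals, exposure_lag)
  temp_lagged <- lagged(series$temp, cov$temp_lag)
  hum_lagged <- if (!is.null(cov$humidity)) {
    if (is.null(series$humidity)) stop("humidity adjustment requested but series has no humidity column")
    lagged(series$humidity, cov$humidity$lag)
  } else NULL

  ok <- !is.na(exp_lagged) & !is.na(temp_lagged)
  if (!is.null(hum_lagged)) ok <- ok & !is.na(hum_lagged)
  if (!is.null(keep_extra)) ok <- ok & keep_extra
  rows <- which(ok)
  if (length(rows) < 50) stop("too few analysis days (", length(rows), ")")

  dates <- series$date[rows]
  tnum <- as.numeric(dates)

  target_edf <- cov$time_df_per_year * years
  blocks <- list()
  if (cov$time_penalized) {
    K <- round(target_edf) + cov$basis_margin
    if (K >= length(rows)) stop("time block: requested df exceeds available days")
    tb <- .time_basis(tnum, K)
    Xt <- tb$B
    St <- tb$S
  } else {
    K <- round(target_edf)
    if (K >= length(rows)) stop("time block: requested df exceeds available days")
    Xt <- splines::ns(tnum, df = K)
    St <- NULL
  }

  Xparts <- list(intercept = matrix(1, length(rows), 1), time = Xt)
  if (cov$dow) {
    dw <- factor(format(dates, "%u"), levels = as.character(1:7))
    M <- stats::model.matrix(~dw)[, -1, drop = FALSE]
    colnames(M) <- paste0("dow", 2:7)
    Xparts$dow <- M
  }
  tv <- temp_lagged[rows]
  if (cov$temp_df >= length(unique(tv))) stop("temperature block: requested df exceeds distinct values")
  Xparts$temp <- splines::ns(tv, df = cov$temp_df)
  if (!is.null(hum_lagged))
    Xparts$humidity <- splines::ns(hum_lagged[rows], df = cov$humidity$df)

  X <- do.call(cbind, lapply(Xparts, unclass))
  cn <- unlist(lapply(names(Xparts), function(nm) {
    k <- ncol(Xparts[[nm]])
    if (k == 1) nm else paste0(nm, seq_len(k))
  }))
  colnames(X) <- cn
  idx <- 0L
  for (nm in names(Xparts)) {
    blocks[[nm]] <- idx + seq_len(ncol(Xparts[[nm]]))
    idx <- idx + ncol(Xparts[[nm]])
  }

  S <- NULL
  if (cov$time_penalized) {
    S <- matrix(0, ncol(X), ncol(X))
    S[blocks$time, blocks$time] <- St
  }

  expo <- if (!is.null(exposure_analysis)) {
    stopifnot(length(exposure_analysis) == length(rows))
    exposure_analysis
  } else exp_lagged[rows]

  structure(list(X = X, exposure = expo, S = S, blocks = blocks,
                 deaths = series$deaths[rows], dates = dates, rows = rows,
                 target_edf = target_edf, penalized = cov$time_penalized,
                 city_id = series$city[1], cov = cov,
                 exposure_lag = exposure_lag),
            class = "mortality_design")
}

#' @export
print.mortality_design <- function(x, ...) {
  cat(sprintf("mortality design for %s: %d days, %d confounder columns (%s)\n",
              x$city_id, length(x$deaths), ncol(x$X),
              if (x$penalized) sprintf("time spline penalised to %.1f edf", x$target_edf)
              else "unpenalised time spline"))
  invisible(x)
}

#' Restrict a series to days below an exposure cutoff
#'
#' Keeps analysis days whose lagged exposure is strictly below `cutoff`
#' (threshold analyses at e.g. 250/125/100/75/60 ug/m3). The returned object
#' retains the full series and original dates; the design stage drops the
#' excluded days and refits the seasonal spline over the kept date range.
#'
#' @param series a `city_series`.
#' @param cutoff ug/m3 (> 0).
#' @param exposure_lag [lag_spec()] used to form the lagged exposure.
#' @return A `restricted_series` (list: `series`, `keep`, `cutoff`,
#'   `exposure_lag`, `n_kept`).
#' @export
restrict_below <- function(series, cutoff,
                           exposure_lag = lag_spec("moving_average", 0:1)) {
  stopifnot(inherits(series, "city_series"), cutoff > 0)
  ev <- lagged(series$pm25, exposure_lag)
  keep <- !is.na(ev) & ev < cutoff
  if (!any(keep)) stop("restriction below ", cutoff, " ug/m3 leaves no days")
  structure(list(series = series, keep = keep, cutoff = cutoff,
                 exposure_lag = exposure_lag, n_kept = sum(keep)),
            class = "restricted_series")
}

#' @export
print.restricted_series <- function(x, ...) {
  cat(sprintf("restricted series (%s): %d of %d days with %s exposure < %g ug/m3\n",
              x$series$city[1], x$n_kept, nrow(x$series),
              format(x$exposure_lag), x$cutoff))
  invisible(x)
}
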
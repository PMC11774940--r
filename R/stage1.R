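# ---- penalized IRLS core -------------------------------------------------

# one penalized IRLS fit of a log-link Poisson mean model at fixed lambda.
# X: full design (confounders + exposure columns), y: counts, S: penalty
# (p x p, zero outside the time block; NULL = unpenalized).
.pirls <- function(X, y, S = NULL, lambda = 0,
                   tol = 1e-8, maxit = 50L, beta0 = NULL) {
  p <- ncol(X)
  pen <- if (is.null(S) || lambda <= 0) matrix(0, p, p) else lambda * S
  beta <- if (is.null(beta0)) {
    b <- numeric(p)
    b[1] <- log(mean(y) + 0.5)
    b
  } else beta0
  dev_old <- Inf
  converged <- FALSE
  dev <- NA_real_
  XtWX <- NULL
  mu <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    XtWX <- crossprod(X * sqrt(mu))
    XtWz <- crossprod(X, mu * z)
    R <- tryCatch(chol(XtWX + pen), error = function(e) NULL)
    if (is.null(R)) {
      R <- chol(XtWX + pen + diag(1e-8 * max(diag(XtWX)), p))
    }
    beta <- backsolve(R, forwardsolve(t(R), XtWz))
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev_old) && abs(dev_old - dev) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  XtWX <- crossprod(X * sqrt(mu))
  list(beta = drop(beta), mu = mu, deviance = dev, XtWX = XtWX,
       iterations = it, converged = converged)
}

# block effective df at given lambda from cached XtWX:
# F = (XtWX + lambda S)^-1 XtWX; edf_j = diag(F)
.edf_profile <- function(XtWX, S, lambda, blocks) {
  p <- ncol(XtWX)
  A <- XtWX + lambda * S
  Fm <- tryCatch(solve(A, XtWX), error = function(e) {
    solve(A + diag(1e-8 * max(diag(XtWX)), p), XtWX)
  })
  d <- diag(Fm)
  list(total = sum(d), time = sum(d[blocks$time]), diag = d)
}

# solve lambda so the time-block edf hits target, at fixed working weights
.solve_lambda <- function(XtWX, S, blocks, target) {
  g <- function(loglam) .edf_profile(XtWX, S, exp(loglam), blocks)$time - target
  lo <- -15; hi <- 30
  if (g(lo) < 0) return(exp(lo))  # even ~no penalty cannot reach target
  if (g(hi) > 0) return(exp(hi))
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-7)$root)
}

#' Fit the city-specific quasi-Poisson regression
#'
#' Penalized iteratively reweighted least squares with log link and Poisson
#' working weights; the ridge-type second-difference penalty acts only on
#' the seasonal-spline block and its smoothing parameter is solved (1-D root
#' find on the block's effective df, iterated with the working weights) so
#' the seasonal term carries the requested df. The dispersion
#' `phi = Pearson chi^2 / (n - total edf)` scales all standard errors by
#' `sqrt(phi)`; point estimates are unaffected. Exposure coefficient
#' covariance uses the sandwich form
#' `phi * (X'WX + lambda S)^-1 X'WX (X'WX + lambda S)^-1`, which reduces to
#' the usual GLM covariance when the penalty is absent.
#'
#' @param design a [build_design()] result.
#' @param deaths optional counts overriding those carried by the design.
#' @param exposure_basis optional matrix replacing the single linear exposure
#'   column (used for spline exposure-response fits); columns are unpenalised.
#' @return A `qpfit` object: coefficients, exposure estimate(s) `beta` with
#'   `se` and `vcov_exposure`, `dispersion`, `edf_total`, `edf_time`,
#'   `lambda`, `n`, `converged`, plus fitted values and diagnostics.
#' @export
fit_quasipoisson <- function(design, deaths = NULL, exposure_basis = NULL) {
  stopifnot(inherits(design, "mortality_design"))
  y <- if (is.null(deaths)) design$deaths else deaths
  if (all(y == 0)) stop("all death counts are zero")
  if (any(y < 0) || any(y != round(y))) stop("deaths must be nonnegative integers")

  E <- if (is.null(exposure_basis)) {
    m <- matrix(design$exposure, ncol = 1)
    colnames(m) <- "exposure"
    m
  } else {
    stopifnot(nrow(exposure_basis) == nrow(design$X))
    exposure_basis
  }
  if (any(!is.finite(E))) stop("exposure contains non-finite values")
  if (stats::sd(E[, 1]) < 1e-12 && ncol(E) == 1)
    stop("exposure is constant; effect is undefined")
  X <- cbind(design$X, E)
  p <- ncol(X)
  pe <- ncol(design$X) + seq_len(ncol(E))  # exposure columns
  blocks <- design$blocks

  if (design$penalized) {
    S <- matrix(0, p, p)
    S[blocks$time, blocks$time] <- design$S[blocks$time, blocks$time]
    lambda <- 1
    fit <- NULL
    for (outer in 1:8) {
      fit <- .pirls(X, y, S, lambda,
                    beta0 = if (is.null(fit)) NULL else fit$beta)
      lam_new <- .solve_lambda(fit$XtWX, S, blocks, design$target_edf)
      if (abs(log(lam_new) - log(lambda)) < 1e-6) { lambda <- lam_new; break }
      lambda <- lam_new
    }
    fit <- .pirls(X, y, S, lambda, beta0 = fit$beta)
  } else {
    S <- NULL
    lambda <- 0
    fit <- .pirls(X, y)
  }

  prof <- if (design$penalized) .edf_profile(fit$XtWX, S, lambda, blocks)
          else list(total = p, time = length(blocks$time),
                    diag = rep(1, p))
  pearson <- sum((y - fit$mu)^2 / fit$mu)
  edf_total <- prof$total + if (design$penalized) 0 else 0
  # exposure columns are unpenalized; include them in the total edf
  n <- length(y)
  dispersion <- pearson / (n - edf_total)

  A <- fit$XtWX + if (design$penalized) lambda * S else 0
  Ainv <- solve(A)
  Vc <- dispersion * (Ainv %*% fit$XtWX %*% Ainv)  # sandwich; = phi*Ainv if lambda=0
  beta_e <- fit$beta[pe]
  V_e <- Vc[pe, pe, drop = FALSE]
  se_e <- sqrt(diag(V_e))

  structure(list(
    city_id = design$city_id,
    coefficients = stats::setNames(fit$beta, colnames(X)),
    beta = unname(beta_e), se = unname(se_e),
    vcov_exposure = V_e, vcov = Vc,
    dispersion = dispersion, pearson = pearson,
    edf_total = edf_total, edf_time = prof$time,
    lambda = lambda, n = n, deviance = fit$deviance,
    converged = fit$converged, iterations = fit$iterations,
    fitted.values = fit$mu, y = y,
    exposure_cols = pe, design = design,
    exposure_names = colnames(E)), class = "qpfit")
}

#' @export
print.qpfit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit (%s): n = %d days, edf = %.1f (time %.1f), phi = %.2f\n",
              x$city_id, x$n, x$edf_total, x$edf_time, x$dispersion))
  if (length(x$beta) == 1) {
    pc <- percent_change(x$beta, x$se)
    cat(sprintf("  exposure: beta = %.4g (se %.3g) per ug/m3; %+.2f%% (%.2f to %.2f) per 10 ug/m3\n",
                x$beta, x$se, pc$estimate, pc$ci_low, pc$ci_high))
  } else {
    cat(sprintf("  exposure basis: %d spline coefficients\n", length(x$beta)))
  }
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.qpfit <- function(object, ...) object$coefficients

#' @export
vcov.qpfit <- function(object, ...) object$vcov

#' @export
fitted.qpfit <- function(object, ...) object$fitted.values

#' @export
residuals.qpfit <- function(object, type = c("pearson", "deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
    pearson = (y - mu) / sqrt(mu),
    deviance = sign(y - mu) * sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))),
    response = y - mu)
}

#' @export
summary.qpfit <- function(object, ...) {
  out <- list(fit = object,
              pct = if (length(object$beta) == 1)
                percent_change(object$beta, object$se) else NULL)
  class(out) <- "summary.qpfit"
  out
}

#' @export
print.summary.qpfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  deviance %.1f, Pearson X2 %.1f, %d IRLS iterations, lambda %.3g\n",
              x$fit$deviance, x$fit$pearson, x$fit$iterations, x$fit$lambda))
  invisible(x)
}

#' Express a log-RR slope as percent change per exposure increment
#'
#' `estimate = (exp(delta * beta) - 1) * 100`, with 95% bounds from
#' `beta +/- 1.96 se` under the same transform.
#'
#' @param beta log-RR per ug/m3.
#' @param se standard error of `beta` (> 0).
#' @param delta exposure increment (default 10 ug/m3).
#' @param conf confidence level (default 0.95; the multiplier is the normal
#'   quantile, 1.959964 at 0.95).
#' @return A one-row data frame with class `percent_change`: `estimate`,
#'   `ci_low`, `ci_high` (percent).
#' @export
percent_change <- function(beta, se, delta = 10, conf = 0.95) {
  stopifnot(all(se > 0))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(
    estimate = (exp(delta * beta) - 1) * 100,
    ci_low = (exp(delta * (beta - zq * se)) - 1) * 100,
    ci_high = (exp(delta * (beta + zq * se)) - 1) * 100)
  class(out) <- c("percent_change", "data.frame")
  out
}

#' One-row tidy summary of a city fit
#'
#' @param fit a `qpfit` with a single linear exposure term.
#' @param label optional label for the lag / exposure used.
#' @return Data frame row: city, label, beta, se, pct_change, ci_low,
#'   ci_high, dispersion, n_days, edf, converged.
#' @export
stage1_row <- function(fit, label = "lag 0-1") {
  stopifnot(inherits(fit, "qpfit"), length(fit$beta) == 1)
  pc <- percent_change(fit$beta, fit$se)
  data.frame(city = fit$city_id, lag = label, beta = fit$beta, se = fit$se,
             pct_change = pc$estimate, ci_low = pc$ci_low, ci_high = pc$ci_high,
             dispersion = fit$dispersion, n_days = fit$n,
             edf = fit$edf_total, converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Fit a panel of lag structures on one series
#'
#' One quasi-Poisson fit per lag specification (e.g. single lags 0, 1, 2 and
#' the 0-3 moving average) on the same series and covariate spec.
#'
#' @param series a `city_series`.
#' @param cov a [cov_spec()].
#' @param lag_specs list of [lag_spec()] objects.
#' @return Data frame with one [stage1_row()] per lag.
#' @export
run_lag_panel <- function(series, cov = cov_spec(),
                          lag_specs = list(lag_spec("moving_average", 0:1))) {
  rows <- lapply(lag_specs, function(ls) {
    d <- build_design(series, cov, exposure_lag = ls)
    stage1_row(fit_quasipoisson(d), label = format(ls))
  })
  do.call(rbind, rows)
}
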
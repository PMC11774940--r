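#' Quadratic B-spline specification for the exposure-response curve
#'
#' Degree-2 B-spline with interior knots at percentiles of the (lagged)
#' exposure distribution; the default single knot at the 50th percentile
#' gives a 3-dimensional basis. Boundary knots sit at the observed exposure
#' min/max. Sensitivity layouts: `c(25, 50, 75)` and `c(10, 50, 90)`.
#'
#' @param knot_percentiles percentiles strictly inside (0, 100), sorted.
#' @param degree B-spline degree (default 2, quadratic).
#' @return A `spline_spec`.
#' @export
spline_spec <- function(knot_percentiles = 50, degree = 2) {
  stopifnot(all(knot_percentiles > 0), all(knot_percentiles < 100),
            !is.unsorted(knot_percentiles, strictly = TRUE), degree >= 1)
  structure(list(degree = as.integer(degree),
                 knot_percentiles = knot_percentiles,
                 knots = NULL, boundary = NULL),
            class = "spline_spec")
}

#' Resolve a spline specification on observed exposures
#'
#' @param spec a [spline_spec()].
#' @param x observed (lagged) exposure values, ug/m3.
#' @return The spec with `knots` (ug/m3) and `boundary` filled in.
#' @export
resolve_spline_spec <- function(spec, x) {
  stopifnot(inherits(spec, "spline_spec"))
  spec$knots <- unname(stats::quantile(x, spec$knot_percentiles / 100, type = 7))
  spec$boundary <- range(x)
  spec
}

# basis of a resolved spec at x, clamped to the boundary (flat extrapolation
# happens at the log-RR level, via clamping before evaluation)
.erc_basis_raw <- function(x, spec) {
  stopifnot(!is.null(spec$knots))
  xc <- pmin(pmax(x, spec$boundary[1]), spec$boundary[2])
  unclass(splines::bs(xc, knots = spec$knots, degree = spec$degree,
                      Boundary.knots = spec$boundary))
}

#' Centered exposure-response basis
#'
#' B-spline basis evaluated at `x` minus its row at `reference`, so that the
#' fitted log relative risk is exactly 0 at the reference concentration.
#' Exposures beyond the resolved boundary are evaluated at the boundary
#' (flat extrapolation).
#'
#' @param x concentrations (ug/m3).
#' @param spec a resolved [spline_spec()].
#' @param reference reference concentration (ug/m3).
#' @return Matrix with one column per basis function.
#' @export
erc_basis <- function(x, spec, reference) {
  B <- .erc_basis_raw(x, spec)
  Bref <- .erc_basis_raw(reference, spec)
  sweep(B, 2, as.numeric(Bref))
}

#' Fit a city-specific exposure-response curve
#'
#' The stage-1 quasi-Poisson regression with the linear exposure term
#' replaced by a centered quadratic B-spline basis of the lagged exposure.
#' Coefficients and their dispersion-scaled covariance define the city
#' curve; predictions at the reference are exactly zero.
#'
#' @param series a `city_series`.
#' @param cov a [cov_spec()].
#' @param exposure_lag [lag_spec()].
#' @param spec a [spline_spec()] (resolved internally on the city's lagged
#'   exposure).
#' @param reference reference concentration; default the city's minimum
#'   lagged exposure.
#' @param grid_n points in the default prediction grid.
#' @return An `erc_curve`: `coeffs`, `vcov`, `spec` (resolved), `reference`,
#'   `range`, `grid`, `predictions` (log-RR with pointwise se), `fit`
#'   diagnostics.
#' @export
fit_city_curve <- function(series, cov = cov_spec(),
                           exposure_lag = lag_spec("moving_average", 0:1),
                           spec = spline_spec(), reference = NULL,
                           grid_n = 50) {
  d <- build_design(series, cov, exposure_lag = exposure_lag)
  x <- d$exposure
  spec <- resolve_spline_spec(spec, x)
  if (is.null(reference)) reference <- min(x)
  B <- erc_basis(x, spec, reference)
  if (qr(B)$rank < ncol(B)) stop("singular exposure basis (too few distinct exposures)")
  colnames(B) <- paste0("erc", seq_len(ncol(B)))
  fit <- fit_quasipoisson(d, exposure_basis = B)
  grid <- seq(spec$boundary[1], spec$boundary[2], length.out = grid_n)
  curve <- structure(list(coeffs = fit$beta, vcov = fit$vcov_exposure,
                          spec = spec, reference = reference,
                          range = spec$boundary, city_id = d$city_id,
                          dispersion = fit$dispersion, n = fit$n,
                          converged = fit$converged),
                     class = "erc_curve")
  curve$grid <- grid
  pr <- predict(curve, grid)
  curve$predictions <- pr
  curve
}

#' Predict from an exposure-response curve
#'
#' @param object an `erc_curve`.
#' @param x concentrations (ug/m3); values beyond the curve's range are
#'   evaluated at the boundary.
#' @param ... unused.
#' @return Data frame: `x`, `log_rr`, `se`, `rr`, `rr_low`, `rr_high`
#'   (pointwise 95%).
#' @export
predict.erc_curve <- function(object, x = object$grid, ...) {
  B <- erc_basis(x, object$spec, object$reference)
  lrr <- drop(B %*% object$coeffs)
  v <- rowSums((B %*% object$vcov) * B)
  se <- sqrt(pmax(v, 0))
  data.frame(x = x, log_rr = lrr, se = se, rr = exp(lrr),
             rr_low = exp(lrr - 1.96 * se), rr_high = exp(lrr + 1.96 * se))
}

#' @export
print.erc_curve <- function(x, ...) {
  cat(sprintf("exposure-response curve (%s): degree %d, knots at %s ug/m3, reference %.1f ug/m3, range %.1f-%.1f\n",
              x$city_id %||% "pooled", x$spec$degree,
              paste(sprintf("%.1f", x$spec$knots), collapse = ", "),
              x$reference, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
plot.erc_curve <- function(x, ...) {
  pr <- x$predictions %||% predict(x)
  plot(pr$x, pr$rr, type = "l", lwd = 2, xlab = "PM2.5 (ug/m3)",
       ylab = "relative risk", ...)
  graphics::lines(pr$x, pr$rr_low, lty = 2)
  graphics::lines(pr$x, pr$rr_high, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}

#' Re-center a curve at a different reference concentration
#'
#' Shifts the log-RR by a constant; relative-risk ratios between any two
#' concentrations are unchanged.
#'
#' @param curve an `erc_curve`.
#' @param reference new reference (ug/m3).
#' @return The re-centered `erc_curve`.
#' @export
recenter_curve <- function(curve, reference) {
  stopifnot(inherits(curve, "erc_curve"))
  curve$reference <- reference
  if (!is.null(curve$grid)) curve$predictions <- predict(curve, curve$grid)
  curve
}

#' Project city curves onto a common basis
#'
#' City-specific curves have city-specific knots and references; before
#' multivariate pooling each curve is evaluated on a dense grid within its
#' own observed range and least-squares-projected onto the common basis
#' (an intercept is included in the projection and discarded, since curves
#' are defined only up to an additive constant). Coefficient covariance is
#' propagated through the linear projection operator.
#'
#' @param curves list of `erc_curve`.
#' @param common a resolved [spline_spec()] on the pooled exposure
#'   distribution.
#' @param reference common reference concentration.
#' @param grid_n grid points per city used for the projection.
#' @return List with one element per city: `coeffs`, `vcov` on the common
#'   basis.
#' @export
project_to_common_basis <- function(curves, common, reference, grid_n = 50) {
  stopifnot(!is.null(common$knots))
  bad <- vapply(curves, function(cu)
    cu$range[1] > common$boundary[2] || cu$range[2] < common$boundary[1],
    logical(1))
  if (any(bad))
    stop("city range does not overlap the common basis: ",
         paste(vapply(curves[bad], function(cu) cu$city_id, character(1)),
               collapse = ", "))
  lapply(curves, function(cu) {
    lo <- max(cu$range[1], common$boundary[1])
    hi <- min(cu$range[2], common$boundary[2])
    grid <- seq(lo, hi, length.out = grid_n)
    G <- erc_basis(grid, cu$spec, cu$reference)      # grid preds = G b
    C <- cbind(1, erc_basis(grid, common, reference))
    # SVD pseudo-inverse: a common-basis direction with no support inside
    # this city's range (zero column) is unidentified here; it gets a zero
    # projected coefficient and a large variance so pooling treats the
    # city as uninformative about it
    sv <- svd(C)
    keep <- sv$d > 1e-10 * sv$d[1]
    P <- sv$v[, keep, drop = FALSE] %*%
      ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
    PG <- (P %*% G)[-1, , drop = FALSE]               # drop intercept row
    V <- PG %*% cu$vcov %*% t(PG)
    if (any(!keep)) {
      N <- sv$v[-1, !keep, drop = FALSE]
      V <- V + N %*% t(N) * 1e2                       # ~sd 10 in log-RR
    }
    list(coeffs = unname(drop(PG %*% cu$coeffs)),
         vcov = unname((V + t(V)) / 2),
         city_id = cu$city_id)
  })
}

#' Multivariate random-effects meta-analysis of curve coefficients
#'
#' Intercept-only multivariate model `y_i ~ N(mu, S_i + Psi)` with the
#' between-city covariance `Psi` estimated by restricted maximum likelihood
#' over its Cholesky parameterization (quasi-Newton), and `mu` by
#' generalized least squares at the estimate. The pooled covariance is
#' `(sum (S_i + Psi)^-1)^-1`.
#'
#' @param city_coeffs list of `list(coeffs, vcov)` on a common basis
#'   (from [project_to_common_basis()]).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum optimizer iterations.
#' @return An `mvmeta_fit`: `mu` (pooled coefficients), `vcov_mu`, `Psi`,
#'   `logLik` (restricted), `converged`, `iterations`, `k`, `dim`.
#' @export
mvmeta_pool <- function(city_coeffs, tol = 1e-9, maxit = 200L) {
  k <- length(city_coeffs)
  Y <- do.call(rbind, lapply(city_coeffs, function(z) z$coeffs))
  Slist <- lapply(city_coeffs, function(z) (z$vcov + t(z$vcov)) / 2)
  p <- ncol(Y)
  if (k < 2) stop("need at least 2 cities")

  gls_mu <- function(Psi) {
    W <- matrix(0, p, p); b <- numeric(p)
    Vinv <- vector("list", k)
    for (i in seq_len(k)) {
      Vi <- Slist[[i]] + Psi
      Vinv[[i]] <- tryCatch(chol2inv(chol(Vi)), error = function(e)
        MASS::ginv(Vi))
      W <- W + Vinv[[i]]
      b <- b + Vinv[[i]] %*% Y[i, ]
    }
    Winv <- tryCatch(chol2inv(chol(W)), error = function(e) MASS::ginv(W))
    list(mu = drop(Winv %*% b), vcov = Winv, Vinv = Vinv, W = W)
  }

  # -2 * restricted log-likelihood (up to a constant)
  m2ll <- function(theta) {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- theta
    diag(L) <- exp(pmin(diag(L), 20))
    Psi <- L %*% t(L)
    g <- gls_mu(Psi)
    val <- 0
    for (i in seq_len(k)) {
      Vi <- Slist[[i]] + Psi
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      r <- Y[i, ] - g$mu
      val <- val + 2 * sum(log(diag(ch))) + drop(r %*% g$Vinv[[i]] %*% r)
    }
    chW <- tryCatch(chol(g$W), error = function(e) NULL)
    if (is.null(chW)) return(1e10)
    val + 2 * sum(log(diag(chW)))
  }

  # start: Cholesky of (empirical between-var minus mean within-var), floored
  Sbar <- Reduce(`+`, Slist) / k
  Psi0 <- stats::cov(Y) - Sbar
  ev <- eigen(Psi0, symmetric = TRUE)
  Psi0 <- ev$vectors %*% diag(pmax(ev$values, max(abs(ev$values)) * 1e-4 + 1e-12),
                              p) %*% t(ev$vectors)
  L0 <- t(chol(Psi0 + diag(1e-10, p)))
  th0 <- L0[lower.tri(L0, diag = TRUE)]
  di <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  is_diag <- di[, 1] == di[, 2]
  th0[is_diag] <- log(pmax(diag(L0), 1e-8))

  opt <- stats::optim(th0, m2ll, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- opt$par
  diag(L) <- exp(pmin(diag(L), 20))
  Psi <- L %*% t(L)
  g <- gls_mu(Psi)
  structure(list(mu = g$mu, vcov_mu = g$vcov, Psi = Psi,
                 logLik = -opt$value / 2, converged = opt$convergence == 0,
                 iterations = opt$counts[1], k = k, dim = p),
            class = "mvmeta_fit")
}

#' @export
print.mvmeta_fit <- function(x, ...) {
  cat(sprintf("multivariate REML meta-analysis: %d cities, dimension %d%s\n",
              x$k, x$dim, if (x$converged) "" else " (NOT converged)"))
  cat("pooled coefficients:", sprintf("%.4g", x$mu), "\n")
  cat("between-city sd (diag Psi^1/2):", sprintf("%.3g", sqrt(diag(x$Psi))), "\n")
  invisible(x)
}

#' Integrated exposure-response curve from pooled coefficients
#'
#' Re-centers the pooled curve so the log relative risk is zero at the
#' chosen reference; pointwise 95% bands come from the pooled coefficient
#' covariance.
#'
#' @param result an [mvmeta_pool()] fit.
#' @param common the resolved common [spline_spec()].
#' @param reference reference concentration (ug/m3), within the grid range.
#' @param grid evaluation concentrations; default 100 points over the
#'   common boundary range.
#' @return An `erc_curve` for the integrated curve.
#' @export
integrated_curve <- function(result, common, reference, grid = NULL) {
  stopifnot(inherits(result, "mvmeta_fit"), !is.null(common$knots))
  if (is.null(grid))
    grid <- seq(common$boundary[1], common$boundary[2], length.out = 100)
  if (reference < min(grid) || reference > max(grid))
    stop("reference must lie within the grid range")
  curve <- structure(list(coeffs = result$mu, vcov = result$vcov_mu,
                          spec = common, reference = reference,
                          range = common$boundary, city_id = NULL,
                          mvmeta = result),
                     class = "erc_curve")
  curve$grid <- grid
  curve$predictions <- predict(curve, grid)
  curve
}

#' Curve export table
#'
#' @param curve an `erc_curve`.
#' @param x optional concentrations.
#' @return Data frame `concentration`, `rr`, `lo`, `hi`.
#' @export
curve_table <- function(curve, x = NULL) {
  pr <- predict(curve, x %||% curve$grid)
  data.frame(concentration = pr$x, rr = pr$rr, lo = pr$rr_low, hi = pr$rr_high)
}
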
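#' Pool city-specific estimates by random-effects meta-analysis
#'
#' Default is the DerSimonian-Laird moment estimator: with fixed-effect
#' weights `w_i = 1/se_i^2`, `Q = sum w_i (b_i - b_FE)^2`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `1/(se_i^2 + tau^2)`, `I^2 = max(0, (Q - (k-1))/Q) * 100`, and a
#' chi-square p-value for Q on k-1 df. `method = "reml"` instead maximizes
#' the restricted likelihood in `tau^2` (1-D optimization) with the same
#' GLS pooling at the estimate.
#'
#' @param beta city log-RR estimates (per ug/m3), or a data frame with
#'   columns `beta` and `se` (e.g. rows from [stage1_row()]), or a list of
#'   `qpfit` objects.
#' @param se standard errors (ignored when `beta` carries them).
#' @param method `"dl"` (DerSimonian-Laird, default) or `"reml"`.
#' @param labels optional city labels.
#' @return A `meta_pool`: `beta_pooled`, `se_pooled`, `tau2`, `Q`, `Q_df`,
#'   `Q_pvalue`, `I2` (percent), `k`, `weights` (normalized random-effects
#'   weights), `method`, plus the inputs.
#' @export
pool <- function(beta, se = NULL, method = c("dl", "reml"), labels = NULL) {
  method <- match.arg(method)
  if (is.list(beta) && !is.data.frame(beta) && inherits(beta[[1]], "qpfit")) {
    labels <- labels %||% vapply(beta, function(f) f$city_id, character(1))
    se <- vapply(beta, function(f) f$se, numeric(1))
    beta <- vapply(beta, function(f) f$beta, numeric(1))
  } else if (is.data.frame(beta)) {
    labels <- labels %||% beta$city
    se <- beta$se
    beta <- beta$beta
  }
  k <- length(beta)
  if (k < 2) stop("need at least 2 estimates to pool")
  stopifnot(length(se) == k, all(se > 0), all(is.finite(beta)))

  w <- 1 / se^2
  b_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fe)^2)
  Q_df <- k - 1
  tau2_dl <- max(0, (Q - Q_df) / (sum(w) - sum(w^2) / sum(w)))

  tau2 <- if (method == "dl") tau2_dl else .reml_tau2(beta, se^2, start = tau2_dl)

  wr <- 1 / (se^2 + tau2)
  b_re <- sum(wr * beta) / sum(wr)
  se_re <- sqrt(1 / sum(wr))
  I2 <- max(0, (Q - Q_df) / Q) * 100
  if (!is.finite(I2)) I2 <- 0

  structure(list(beta_pooled = b_re, se_pooled = se_re, tau2 = tau2,
                 Q = Q, Q_df = Q_df,
                 Q_pvalue = stats::pchisq(Q, Q_df, lower.tail = FALSE),
                 I2 = I2, k = k, weights = wr / sum(wr), method = method,
                 beta = beta, se = se,
                 labels = labels %||% paste0("study", seq_len(k))),
            class = "meta_pool")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# univariate REML for tau^2: maximize the restricted log-likelihood
# -0.5 [ sum log(v_i+t) + log sum 1/(v_i+t) + sum (b_i-mu)^2/(v_i+t) ]
.reml_tau2 <- function(beta, v, start = 0) {
  nll <- function(t) {
    vi <- v + t
    w <- 1 / vi
    mu <- sum(w * beta) / sum(w)
    0.5 * (sum(log(vi)) + log(sum(w)) + sum(w * (beta - mu)^2))
  }
  hi <- max(stats::var(beta) * 10, max(v) * 10, start * 10, 1e-12)
  opt <- stats::optimize(nll, c(0, hi), tol = 1e-14)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' @export
print.meta_pool <- function(x, ...) {
  pc <- percent_change(x$beta_pooled, x$se_pooled)
  cat(sprintf("random-effects pooling (%s) of %d cities:\n", toupper(x$method), x$k))
  cat(sprintf("  pooled beta = %.4g (se %.3g) per ug/m3; %+.2f%% (%.2f to %.2f) per 10 ug/m3\n",
              x$beta_pooled, x$se_pooled, pc$estimate, pc$ci_low, pc$ci_high))
  cat(sprintf("  tau2 = %.3g, Q = %.2f on %d df (p = %.3g), I2 = %.1f%%\n",
              x$tau2, x$Q, x$Q_df, x$Q_pvalue, x$I2))
  invisible(x)
}

#' Forest-plot-ready table of city estimates plus the pooled row
#'
#' @param pooled a [pool()] result.
#' @return Data frame: one row per city (percent change per 10 ug/m3 with
#'   95% CI and normalized weight) and a final `POOLED` row.
#' @export
forest_table <- function(pooled) {
  stopifnot(inherits(pooled, "meta_pool"))
  rows <- percent_change(pooled$beta, pooled$se)
  out <- data.frame(city = pooled$labels, beta = pooled$beta, se = pooled$se,
                    pct_change = rows$estimate, ci_low = rows$ci_low,
                    ci_high = rows$ci_high, weight = pooled$weights,
                    stringsAsFactors = FALSE)
  pc <- percent_change(pooled$beta_pooled, pooled$se_pooled)
  rbind(out, data.frame(city = "POOLED", beta = pooled$beta_pooled,
                        se = pooled$se_pooled, pct_change = pc$estimate,
                        ci_low = pc$ci_low, ci_high = pc$ci_high,
                        weight = 1))
}
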
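# Independent oracles, coded separately from the package internals.

# Newton-Raphson scoring for a log-link Poisson GLM, with quasi-Poisson
# dispersion from Pearson residuals and edf = ncol(X). Deliberately written
# as explicit score/information iterations, not IRLS with a working response.
oracle_glm_poisson <- function(X, y, tol = 1e-12, maxit = 100) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- log(mean(y))
  for (it in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(t(X) %*% (y - mu))
    info <- t(X) %*% (X * mu)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(drop(X %*% beta))
  phi <- sum((y - mu)^2 / mu) / (length(y) - p)
  se <- sqrt(phi * diag(solve(t(X) %*% (X * mu))))
  list(beta = beta, se = se, dispersion = phi, iterations = it)
}

# closed-form two-study DerSimonian-Laird pooling
oracle_dl_two_study <- function(b1, b2, s1, s2) {
  w1 <- 1 / s1^2; w2 <- 1 / s2^2
  bfe <- (w1 * b1 + w2 * b2) / (w1 + w2)
  Q <- w1 * (b1 - bfe)^2 + w2 * (b2 - bfe)^2
  sw <- w1 + w2
  tau2 <- max(0, (Q - 1) / (sw - (w1^2 + w2^2) / sw))
  wr1 <- 1 / (s1^2 + tau2); wr2 <- 1 / (s2^2 + tau2)
  list(pooled = (wr1 * b1 + wr2 * b2) / (wr1 + wr2),
       se = sqrt(1 / (wr1 + wr2)),
       Q = Q, tau2 = tau2,
       I2 = max(0, (Q - 1) / Q) * 100)
}

# day-by-day attributable deaths loop (naive reference implementation)
oracle_af_loop <- function(deaths, exposure, curve, reference) {
  total <- 0
  for (t in seq_along(deaths)) {
    if (exposure[t] <= reference) next
    b <- airmort::erc_basis(exposure[t], curve$spec, reference)
    rr <- exp(sum(b * curve$coeffs))
    if (rr < 1) rr <- 1
    total <- total + deaths[t] * (rr - 1) / rr
  }
  total
}
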
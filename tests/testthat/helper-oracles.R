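# Independent re-derivations used as oracles. These deliberately repeat the
# textbook formulas in plain vector arithmetic, without calling any mrpool
# pooling/regression code, so that implementation and check stay separate.

# DerSimonian-Laird chain, brute force.
dl_oracle <- function(theta, se, ci_level = 0.95) {
  k <- length(theta)
  w <- 1 / se^2
  fixed <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - fixed)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * theta) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  z <- qnorm(1 - (1 - ci_level) / 2)
  list(pooled = mu, se = se_mu, ci = c(mu - z * se_mu, mu + z * se_mu),
       q = q, tau2 = tau2,
       i2 = if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0,
       p_het = pchisq(q, k - 1, lower.tail = FALSE))
}

# Egger intercept by explicit normal equations (no lm).
egger_oracle <- function(theta, se) {
  y <- theta / se
  x <- 1 / se
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  k <- length(y)
  s2 <- sum(resid^2) / (k - 2)
  covb <- s2 * solve(t(X) %*% X)
  intercept <- beta[1]
  ise <- sqrt(covb[1, 1])
  t <- intercept / ise
  list(intercept = intercept, intercept_se = ise, slope = beta[2],
       t = t, p = 2 * pt(-abs(t), k - 2))
}

rand_estimates <- function(k, scale = "log_odds_ratio") {
  lapply(seq_len(k), function(i)
    effect_estimate(rnorm(1, 0, 1), runif(1, 0.05, 0.8), scale = scale,
                    study_id = paste0("s", i)))
}

est_vec <- function(estimates, field) {
  if (field == "study_id") vapply(estimates, `[[`, character(1), field)
  else vapply(estimates, `[[`, numeric(1), field)
}
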
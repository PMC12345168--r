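# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::cor) so implementation and oracle can disagree.

# Pearson via raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# OLS of y on x by explicit normal equations; returns slope, intercept,
# r_squared, and residual scale with n - 2 df
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sse / sst,
       s = sqrt(sse / (length(x) - 2)),
       z = as.numeric((y - fitted) / sqrt(sse / (length(x) - 2))))
}

# Exact signed-rank p by enumerating all 2^n sign assignments (n <= ~15)
oracle_signed_rank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, 0)
  p_ge <- mean(ws >= w_obs)
  p_le <- mean(ws <= w_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
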
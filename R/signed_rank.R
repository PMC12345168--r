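# Paired Wilcoxon signed-rank test with an exact null distribution.
#
# The exact tail is computed by dynamic programming over the rank
# generating function. Ranks of |d| are averaged over ties, so they can be
# half-integers; doubling them makes every achievable statistic an integer,
# which keeps the DP exact in floating point (counts stay far below 2^53
# for the n <= 50 exact regime).

#' Exact paired Wilcoxon signed-rank test
#'
#' Tests whether paired `after` values systematically exceed (or differ
#' from) `before` values. Zero differences are dropped (Wilcoxon
#' convention); tied absolute differences receive average ranks. The null
#' distribution of the positive-rank sum is enumerated exactly for up to 50
#' nonzero pairs; beyond that a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param before,after Paired numeric vectors. When `after` is `NULL`,
#'   `before` is interpreted as the vector of differences
#'   `d = after - before` itself.
#' @param alternative `"greater"` (after > before), `"less"`, or
#'   `"two.sided"`.
#' @return List with `statistic` (positive-rank sum W+), `n` (nonzero
#'   pairs), `p_value`, `method` (`"exact"` or `"normal"`), `degenerate`
#'   (`TRUE` when all differences are zero, in which case `p_value` is
#'   `NA`), and `n_zero` (dropped zero differences).
#' @export
signed_rank_test <- function(before, after = NULL,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(after)) as.numeric(before) else as.numeric(after) - as.numeric(before)
  assert_that(all(is.finite(d)), "signed_rank_test: non-finite differences")
  assert_that(length(d) >= 1L, "signed_rank_test: no pairs")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, n = 0L, p_value = NA_real_,
                method = "degenerate", degenerate = TRUE, n_zero = n_zero))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 50L) {
    w2 <- as.integer(round(2 * w))
    # counts[s + 1] = number of sign assignments with doubled rank sum s
    counts <- signed_rank_null_counts(r)
    denom <- 2^n
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / denom
    p_le <- sum(counts[seq_len(w2 + 1L)]) / denom
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p_ge <- stats::pnorm((w - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((w + 0.5 - mu) / sigma)
    method <- "normal"
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w, n = n, p_value = p, method = method,
       degenerate = FALSE, n_zero = n_zero)
}

# Exact null distribution of the doubled positive-rank sum for a vector of
# average ranks; exposed internally for oracle tests.
signed_rank_null_counts <- function(r) {
  r2 <- as.integer(round(2 * r))
  counts <- numeric(sum(r2) + 1L)
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
    counts <- counts + shifted
  }
  counts
}
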
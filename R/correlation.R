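# Rank/linear correlation machinery, binned scatter summaries, and
# pairwise cross-condition ortholog correlation matrices.

check_xy <- function(x, y, what) {
  assert_that(length(x) == length(y), "%s: x and y lengths differ", what)
  assert_that(length(x) >= 3L, "%s: need at least 3 observations", what)
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "%s: non-finite values", what)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @return A `correlation_result`: list with `rho`, `method`, `n`.
#' @export
spearman <- function(x, y) {
  check_xy(x, y, "spearman")
  rx <- rank(x)
  ry <- rank(y)
  assert_that(stats::sd(rx) > 0 && stats::sd(ry) > 0,
              "spearman: correlation undefined (zero variance in ranks)")
  structure(list(rho = stats::cor(rx, ry), method = "spearman",
                 n = length(x)),
            class = "correlation_result")
}

#' Linear fit and coefficient of determination
#'
#' Ordinary least squares of `y` on `x` (closed form), reporting the
#' Pearson correlation and the R-squared (= 1 - SSE/SST = Pearson rho
#' squared for a simple linear fit).
#'
#' @inheritParams spearman
#' @return A `correlation_result` with `rho` (Pearson), `r_squared`,
#'   `slope`, `intercept`, `n`.
#' @export
fit_r_squared <- function(x, y) {
  check_xy(x, y, "fit_r_squared")
  sxx <- sum((x - mean(x))^2)
  assert_that(sxx > 0, "fit_r_squared: zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - intercept - slope * x)^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  rho <- if (sst > 0) sxy / sqrt(sxx * sst) else NA_real_
  structure(list(rho = rho, method = "pearson", n = length(x),
                 r_squared = r2, slope = slope, intercept = intercept),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s rho = %.4f (n = %d)%s\n",
              x$method, x$rho, x$n,
              if (!is.null(x$r_squared)) sprintf(", R2 = %.4f", x$r_squared) else ""))
  invisible(x)
}

#' Two-dimensional binned scatter summary
#'
#' Histogram of (x, y) points over a rectangular grid; points falling
#' outside the edges are clipped into the boundary bins, so the grid total
#' always equals the number of points.
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_edges,y_edges Strictly increasing bin edges.
#' @return Integer matrix of counts, rows indexed by x bins (left edges as
#'   dimnames), columns by y bins.
#' @export
binned_scatter <- function(x, y, x_edges, y_edges = x_edges) {
  assert_that(length(x) == length(y), "binned_scatter: lengths differ")
  for (e in list(x_edges, y_edges)) {
    assert_that(length(e) >= 2L && all(diff(e) > 0),
                "binned_scatter: edges must be strictly increasing")
  }
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ix <- clamp(findInterval(x, x_edges, rightmost.closed = TRUE), 1L, nx)
  iy <- clamp(findInterval(y, y_edges, rightmost.closed = TRUE), 1L, ny)
  counts <- matrix(0L, nx, ny,
                   dimnames = list(format(x_edges[-(nx + 1L)]),
                                   format(y_edges[-(ny + 1L)])))
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  counts
}

#' Pairwise ortholog correlation matrices
#'
#' For each pair of conditions, restricts to orthogroups that are
#' single-copy in both conditions and whose genes are paired-detected (both
#' mRNA and protein) in both, then computes the Spearman correlation of the
#' chosen modality's log2 values across those orthogroups.
#'
#' @param pairs Named list of `profile_pair` objects keyed by condition id.
#' @param map An `ortholog_map` covering those conditions.
#' @param modality `"mRNA"` or `"protein"`.
#' @return A `pair_matrix`: list with symmetric matrices `n` (ortholog
#'   counts; diagonal = per-condition usable orthologs) and `rho`
#'   (Spearman; diagonal 1; `NA` where fewer than 3 shared orthologs or the
#'   correlation is undefined).
#' @export
pairwise_ortholog_matrix <- function(pairs, map, modality = c("mRNA", "protein")) {
  modality <- match.arg(modality)
  assert_that(length(pairs) >= 2L, "need at least 2 profiles")
  conds <- names(pairs)
  # per condition: orthogroup -> value of its single-copy paired gene
  og_values <- lapply(conds, function(cond) {
    pair <- pairs[[cond]]
    sc <- single_copy_genes(map, cond)          # gene -> og
    sc <- sc[names(sc) %in% pair$paired_ids]
    vals <- paired_values(pair, names(sc))
    v <- if (modality == "mRNA") vals$r else vals$p
    stats::setNames(as.numeric(v), unname(sc))
  })
  names(og_values) <- conds
  k <- length(conds)
  nmat <- matrix(0L, k, k, dimnames = list(conds, conds))
  rmat <- matrix(NA_real_, k, k, dimnames = list(conds, conds))
  for (i in seq_len(k)) {
    nmat[i, i] <- length(og_values[[i]])
    rmat[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      shared <- intersect(names(og_values[[i]]), names(og_values[[j]]))
      nmat[i, j] <- nmat[j, i] <- length(shared)
      if (length(shared) >= 3L) {
        xi <- og_values[[i]][shared]
        xj <- og_values[[j]][shared]
        if (stats::sd(rank(xi)) > 0 && stats::sd(rank(xj)) > 0) {
          rmat[i, j] <- rmat[j, i] <- spearman(xi, xj)$rho
        }
      }
    }
  }
  structure(list(n = nmat, rho = rmat, modality = modality),
            class = "pair_matrix")
}

#' Compare cross-condition conservation of protein vs mRNA
#'
#' Over all off-diagonal condition pairs, counts how often the protein
#' correlation exceeds the mRNA correlation, and tests the paired
#' differences with the one-sided exact Wilcoxon signed-rank test.
#'
#' @param rho_mrna,rho_protein `pair_matrix` objects sharing labels.
#' @return List with `wins` (protein > mRNA count), `n_pairs`, `p_value`
#'   (one-sided, protein greater), and the full `test` result.
#' @export
compare_protein_vs_mrna_conservation <- function(rho_mrna, rho_protein) {
  stopifnot(inherits(rho_mrna, "pair_matrix"), inherits(rho_protein, "pair_matrix"))
  assert_that(identical(rownames(rho_mrna$rho), rownames(rho_protein$rho)),
              "pair matrices have mismatched condition labels")
  ut <- upper.tri(rho_mrna$rho)
  m <- rho_mrna$rho[ut]
  p <- rho_protein$rho[ut]
  keep <- is.finite(m) & is.finite(p)
  m <- m[keep]; p <- p[keep]
  test <- signed_rank_test(before = m, after = p, alternative = "greater")
  list(wins = sum(p > m), n_pairs = length(m),
       p_value = test$p_value, test = test)
}
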
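# Correlation machinery: Spearman with ties, OLS/R-squared, binned
# scatter, pairwise ortholog matrices, protein-vs-mRNA conservation.

test_that("spearman handles perfect, reversed, and tied rankings", {
  expect_equal(spearman(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman(1:3, c(3, 2, 1))$rho, -1)
  # hand Pearson on average ranks [1, 2.5, 2.5, 4] vs [1, 2, 3, 4]
  expect_equal(spearman(c(1, 2, 2, 3), 1:4)$rho, 4.5 / sqrt(4.5 * 5),
               tolerance = 1e-12)
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(c(1, 1, 1), 1:3), "zero variance")
  expect_error(spearman(1:3, c(1, NA, 3)), "non-finite")
})

test_that("fit_r_squared matches hand-computed OLS", {
  perfect <- fit_r_squared(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)

  fit <- fit_r_squared(c(0, 1, 2), c(0, 1, 1))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.75, tolerance = 1e-12)

  expect_error(fit_r_squared(c(2, 2, 2), 1:3), "zero variance")
})

test_that("r_squared of independent noise vanishes at large n", {
  r2 <- vapply(1:10, function(s) {
    set.seed(s)
    fit_r_squared(rnorm(10000), rnorm(10000))$r_squared
  }, 0)
  expect_lt(mean(r2), 0.02)
})

test_that("spearman and OLS match brute-force oracles on random tied data", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- sample(round(rnorm(n), 1))   # rounding induces ties
    y <- round(rnorm(n, x), 1)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0 || sd(x) == 0) next
    expect_equal(spearman(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
    o <- oracle_ols(x, y)
    f <- fit_r_squared(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-12)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-12)
    expect_equal(f$rho^2, f$r_squared, tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30, x)
    base <- spearman(x, y)$rho
    expect_equal(spearman(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman(x, rank(y))$rho, base, tolerance = 1e-12)
    expect_equal(spearman(2 * x + 5, exp(y))$rho, base, tolerance = 1e-12)
  }
})

test_that("binned_scatter conserves counts and clips to boundary bins", {
  edges <- 0:4
  g <- binned_scatter(rep(0.5, 4), rep(2.5, 4), edges)
  expect_equal(g[1, 3], 4L)
  expect_equal(sum(g), 4L)

  set.seed(1)
  x <- rnorm(500, 2, 3); y <- rnorm(500, 2, 3)  # many points out of range
  expect_equal(sum(binned_scatter(x, y, edges)), 500L)

  # shifting by one bin width shifts the interior grid one cell
  x2 <- runif(200, 1, 2); y2 <- runif(200, 1, 2)
  g1 <- binned_scatter(x2, y2, edges)
  g2 <- binned_scatter(x2 + 1, y2 + 1, edges)
  expect_equal(unname(g1[2, 2]), unname(g2[3, 3]))

  expect_error(binned_scatter(1, 1, c(0, 0, 1)), "strictly increasing")
})

# three conditions with nested ortholog sets
nested_fixture <- function() {
  conds <- c("A", "B", "C")
  ogs <- sprintf("OG%02d", 1:12)
  groups <- lapply(seq_along(ogs), function(i) {
    covered <- switch((i %% 3) + 1, conds, c("A", "B"), "A")
    stats::setNames(lapply(covered, function(cond) paste0(cond, "_", ogs[i])),
                    covered)
  })
  names(groups) <- ogs
  map <- ortholog_map(groups, conds)
  set.seed(99)
  pairs <- lapply(conds, function(cond) {
    genes <- vapply(map$groups, function(g) {
      if (!is.null(g[[cond]])) g[[cond]] else NA_character_
    }, "")
    genes <- genes[!is.na(genes)]
    make_pair(rnorm(length(genes)), rnorm(length(genes)),
              condition = cond, genes = unname(genes))
  })
  names(pairs) <- conds
  list(map = map, pairs = pairs)
}

test_that("pairwise ortholog matrices match brute-force set intersection", {
  fx <- nested_fixture()
  pm <- pairwise_ortholog_matrix(fx$pairs, fx$map, "mRNA")
  expect_equal(pm$n, t(pm$n))
  expect_equal(pm$rho, t(pm$rho))
  expect_equal(unname(diag(pm$rho)), rep(1, 3))
  # brute force: count orthogroups with single-copy paired genes in both
  brute <- function(c1, c2) {
    sum(vapply(fx$map$groups, function(g) {
      length(g[[c1]]) == 1L && length(g[[c2]]) == 1L &&
        g[[c1]] %in% fx$pairs[[c1]]$paired_ids &&
        g[[c2]] %in% fx$pairs[[c2]]$paired_ids
    }, TRUE))
  }
  for (c1 in rownames(pm$n)) for (c2 in colnames(pm$n)) {
    if (c1 != c2) expect_equal(pm$n[c1, c2], brute(c1, c2))
  }
})

test_that("identical ortholog values give rho 1; tiny overlaps give NA", {
  conds <- c("A", "B")
  groups <- stats::setNames(lapply(1:5, function(i) {
    list(A = paste0("A_g", i), B = paste0("B_g", i))
  }), paste0("OG", 1:5))
  map <- ortholog_map(groups, conds)
  vals <- c(1.2, 3.4, 0.5, 2.2, 5.0)
  pairs <- list(
    A = make_pair(vals, vals, condition = "A", genes = paste0("A_g", 1:5)),
    B = make_pair(vals, vals, condition = "B", genes = paste0("B_g", 1:5)))
  pm <- pairwise_ortholog_matrix(pairs, map, "protein")
  expect_equal(pm$rho["A", "B"], 1)

  # shrink overlap below 3 -> undefined marker, not an error
  pairs$B <- make_pair(vals[1:2], vals[1:2], condition = "B",
                       genes = paste0("B_g", 1:2))
  pm2 <- pairwise_ortholog_matrix(pairs, map, "protein")
  expect_true(is.na(pm2$rho["A", "B"]))
  expect_equal(pm2$n["A", "B"], 2L)
})

test_that("protein-vs-mRNA conservation comparison counts wins and tests them", {
  k <- 9
  conds <- paste0("c", 1:k)
  base <- matrix(0.4, k, k, dimnames = list(conds, conds)); diag(base) <- 1
  mk <- function(m) structure(list(n = base * 0 + 50L, rho = m,
                                   modality = "x"), class = "pair_matrix")
  set.seed(3)
  noise <- matrix(0, k, k)
  noise[upper.tri(noise)] <- runif(k * (k - 1) / 2, 0, 0.05)
  noise <- noise + t(noise)
  mrna <- mk(base + noise)

  same <- compare_protein_vs_mrna_conservation(mrna, mrna)
  expect_equal(same$wins, 0L)
  expect_true(same$test$degenerate)

  up <- mk(base + noise + 0.1)
  cmp <- compare_protein_vs_mrna_conservation(mrna, up)
  expect_equal(cmp$wins, 36L)
  expect_equal(cmp$p_value, 2^-36, tolerance = 1e-15)

  # 34 of 36 pairs improve
  mixed <- base + noise + 0.1
  flip <- which(upper.tri(mixed), arr.ind = TRUE)[1:2, ]
  mixed[flip] <- (base + noise)[flip] - 0.05
  mixed[flip[, 2:1]] <- mixed[flip]
  cmp34 <- compare_protein_vs_mrna_conservation(mrna, mk(mixed))
  expect_equal(cmp34$wins, 34L)
  expect_lt(cmp34$p_value, 1e-4)

  bad <- mk(base)
  rownames(bad$rho) <- colnames(bad$rho) <- paste0("x", 1:k)
  expect_error(compare_protein_vs_mrna_conservation(mrna, bad), "mismatch")
})
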
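# Genome-wide ptr regression, standardized residuals, outlier classes,
# conserved cross-condition ranking.

test_that("fit_ptr_regression matches hand OLS and behaves under shifts", {
  ident <- fit_ptr_regression(make_pair(1:5, 1:5))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$s, 0)

  fit <- fit_ptr_regression(make_pair(c(0, 1, 2), c(0, 1, 1)))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(fit$s, sqrt(1 / 6), tolerance = 1e-12)

  shifted <- fit_ptr_regression(make_pair(c(0, 1, 2), c(0, 1, 1) + 3.5))
  expect_equal(shifted$slope, fit$slope)
  expect_equal(shifted$intercept, fit$intercept + 3.5, tolerance = 1e-12)
  expect_equal(shifted$s, fit$s, tolerance = 1e-12)

  expect_error(fit_ptr_regression(make_pair(1:2, 1:2)), ">= 3")
  expect_error(fit_ptr_regression(make_pair(c(1, 1, 1), 1:3)), "zero variance")
})

test_that("standardized residuals reproduce the derived 3-point example", {
  pair <- make_pair(c(0, 1, 2), c(0, 1, 1))
  recs <- standardized_residuals(fit_ptr_regression(pair), pair)
  expect_equal(recs$z, c(-1 / 6, 1 / 3, -1 / 6) / sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(recs$ptr, c(0, 0, -1))
  expect_equal(recs$class, rep("none", 3))

  # perfect fit: s = 0, all z defined as 0
  perfect <- make_pair(1:4, (1:4) * 2)
  recs0 <- standardized_residuals(fit_ptr_regression(perfect), perfect)
  expect_equal(recs0$z, rep(0, 4))
  expect_equal(recs0$class, rep("none", 4))
})

test_that("class thresholds sit exactly at |z| = 2", {
  # build data whose z values hit 2.0, -2.0, 1.99 by construction:
  # fake a model with slope 0, intercept 0, s = 1
  pair <- make_pair(rep(c(1, 2, 3, 4), 5), rep(0, 20))
  model <- structure(list(condition_id = "C1", slope = 0, intercept = 0,
                          s = 1, n = 20, genes = pair$paired_ids),
                     class = "ptr_regression")
  pair$protein$value <- c(2, -2, 1.99, -1.99, rep(0, 16))
  pair2 <- profile_pair("C1", pair$mrna, pair$protein)
  recs <- standardized_residuals(model, pair2)
  expect_equal(recs$class[1:4], c("high", "low", "none", "none"))
})

test_that("z vector has mean zero and the analytic sample variance", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    pair <- make_pair(rnorm(n), rnorm(n), genes = sprintf("g%04d", 1:n))
    recs <- standardized_residuals(fit_ptr_regression(pair), pair)
    expect_lt(abs(mean(recs$z)), 1e-10)
    # sum(z^2) = SSE / s^2 = n - 2, so the sample variance is (n-2)/(n-1)
    expect_equal(var(recs$z), (n - 2) / (n - 1), tolerance = 1e-10)
  }
})

test_that("standardized residuals match the normal-equations oracle", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n, 0.8 * x), 1)
    if (sd(x) == 0) next
    pair <- make_pair(x, y, genes = sprintf("g%04d", 1:n))
    recs <- standardized_residuals(fit_ptr_regression(pair), pair)
    expect_equal(recs$z, oracle_ols(x, y)$z, tolerance = 1e-12)
  }
})

test_that("outlier counts ignore 'none' and survive shifts of either axis", {
  pair <- make_pair(rnorm(50), rnorm(50), genes = sprintf("g%03d", 1:50))
  count_of <- function(p) {
    r <- standardized_residuals(fit_ptr_regression(p), p)
    count_outlier_classes(stats::setNames(list(r), "C1"))
  }
  base <- count_of(pair)
  shift <- make_pair(pair$mrna$value + 4, pair$protein$value - 2,
                     genes = pair$paired_ids)
  expect_equal(count_of(shift)[, c("low", "high")], base[, c("low", "high")])

  fake <- data.frame(gene_id = c("a", "b", "c"), orthogroup = NA,
                     ptr = 0, z = c(2.5, -2.5, 0),
                     class = c("high", "low", "none"))
  class(fake) <- c("outlier_records", "data.frame")
  attr(fake, "condition_id") <- "X"
  cnt <- count_outlier_classes(fake)
  expect_equal(cnt$low, 1L)
  expect_equal(cnt$high, 1L)

  empty <- fake[0, ]
  class(empty) <- c("outlier_records", "data.frame")
  attr(empty, "condition_id") <- "X"
  expect_equal(count_outlier_classes(empty)[, c("low", "high")],
               data.frame(low = 0L, high = 0L))
})

# hand-built records for two conditions over a small map
ranking_fixture <- function(z_by_og) {
  conds <- c("A", "B")
  ogs <- rownames(z_by_og)
  groups <- stats::setNames(lapply(ogs, function(og) {
    list(A = paste0("A_", og), B = paste0("B_", og))
  }), ogs)
  map <- ortholog_map(groups, conds)
  records <- lapply(conds, function(cond) {
    df <- data.frame(gene_id = paste0(cond, "_", ogs), orthogroup = ogs,
                     ptr = z_by_og[, cond], z = z_by_og[, cond],
                     class = "none", stringsAsFactors = FALSE)
    class(df) <- c("outlier_records", "data.frame")
    attr(df, "condition_id") <- cond
    df
  })
  names(records) <- conds
  list(map = map, records = records)
}

test_that("conserved ranking clips at +/-2 before averaging and sorts deterministically", {
  z <- matrix(c(3, 1, -5, 1, 0.5, 0.5), 3, 2, byrow = TRUE,
              dimnames = list(c("OG1", "OG2", "OG3"), c("A", "B")))
  fx <- ranking_fixture(z)
  rk <- conserved_ranking(fx$records, fx$map, k = 2)
  mz <- rk$mean_z
  expect_equal(unname(mz["OG1"]), 1.5)   # (clip(3) + 1) / 2
  expect_equal(unname(mz["OG2"]), -0.5)  # (clip(-5) + 1) / 2
  expect_equal(rk$ranking$orthogroup, c("OG1", "OG3", "OG2"))
  expect_equal(rk$top, c("OG1", "OG3"))
  expect_equal(rk$bottom, c("OG2", "OG3"))
})

test_that("orthogroups missing a condition's residual are excluded with report", {
  z <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("OG1", "OG2"), c("A", "B")))
  fx <- ranking_fixture(z)
  # drop OG2's record in condition B
  fx$records$B <- fx$records$B[fx$records$B$orthogroup != "OG2", ]
  rk <- conserved_ranking(fx$records, fx$map)
  expect_equal(rk$excluded, "OG2")
  expect_equal(rownames(rk$z), "OG1")
  expect_error(conserved_ranking(fx$records, fx$map, conditions = c("A", "Z")),
               "missing outlier records")
})

test_that("injected conserved outliers are recovered into the extreme lists", {
  hits <- 0; n_inj <- 0
  for (seed in 1:5) {
    study <- generate_study(noise_free_config(
      n_conditions = 3, genes_per_condition = 200, n_orthogroups = 60,
      n_shared_all = 60, n_shared_bacterial = 0,
      outlier_fraction = 0.15, seed = seed + 100))
    pairs <- lapply(study$tables, function(t)
      aggregate_and_filter(t$mrna, t$protein))
    recs <- lapply(pairs, function(p)
      standardized_residuals(fit_ptr_regression(p), p, study$map))
    rk <- conserved_ranking(recs, study$map, k = 15)
    truth <- study$truth$orthogroups
    inj <- truth$orthogroup[truth$outlier & abs(truth$c) >= 4 &
                              truth$orthogroup %in% rownames(rk$z)]
    for (og in inj) {
      n_inj <- n_inj + 1
      sgn <- truth$outlier_sign[truth$orthogroup == og]
      hits <- hits + (if (sgn > 0) og %in% rk$top else og %in% rk$bottom)
    }
  }
  expect_gt(n_inj, 0)
  expect_gte(hits / n_inj, 0.9)
})
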
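# Synthetic study generator: noise-free identities, reproducibility,
# dropout monotonicity, ground-truth conversion factors, and the
# distributional invariants the downstream analyses rely on.

test_that("noise-free limit: raw log2(protein) - log2(mRNA) equals c_j everywhere", {
  study <- generate_study(noise_free_config(
    genes_per_condition = 300, n_orthogroups = 80,
    n_shared_all = 20, n_shared_bacterial = 10, n_conditions = 5, seed = 3))
  c_j <- with(study$truth$orthogroups, stats::setNames(c, orthogroup))
  for (cond in names(study$tables)) {
    tab <- study$tables[[cond]]
    sc <- rtpfactor:::single_copy_genes(study$map, cond)  # gene -> og
    for (rep in 1:4) {
      ptr <- log2(tab$protein$values[names(sc), rep]) -
        log2(tab$mrna$values[names(sc), rep])
      expect_equal(unname(ptr), unname(c_j[sc]), tolerance = 1e-9)
    }
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 17)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$map, s2$map)
  s3 <- generate_study(tiny_config(seed = 18))
  expect_false(identical(s1$tables, s3$tables))
})

test_that("raising the dropout midpoint strictly lowers detected-protein fraction", {
  det_frac <- function(study) {
    vals <- do.call(rbind, lapply(study$tables, function(t) t$protein$values))
    mean(vals > 0)
  }
  fr_lo <- fr_hi <- numeric(20)
  for (s in 1:20) {
    fr_lo[s] <- det_frac(generate_study(tiny_config(seed = s)))
    fr_hi[s] <- det_frac(generate_study(tiny_config(seed = s,
                                                    protein_dropout_midpoint = 8)))
  }
  # same seed stream for abundances: detection with the higher midpoint is
  # a subset of detection with the lower one, per seed
  expect_true(all(fr_hi <= fr_lo))
  expect_lt(mean(fr_hi), mean(fr_lo))
})

test_that("truth_rtp composes c_j and subset means of d_ij", {
  og <- c("OG1", "OG2")
  truth <- structure(list(
    orthogroups = data.frame(orthogroup = og, c = c(1.5, -0.5)),
    d = matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(og, c("A", "B"))),
    condition_ids = c("A", "B")), class = "synthetic_truth")
  # symmetric deviations cancel over both conditions
  expect_equal(truth_rtp(truth, c("A", "B")),
               stats::setNames(c(1.5, -0.5), og))
  # single condition: c_j + d_ij
  expect_equal(truth_rtp(truth, "A"), stats::setNames(c(2.5, -1.5), og))
  expect_error(truth_rtp(truth, "Z"), "unknown condition")
  expect_error(truth_rtp(truth, character(0)), "empty")

  # d == 0 everywhere: truth equals c_j, from a real generated study
  study <- generate_study(noise_free_config(n_conditions = 3,
    genes_per_condition = 120, n_orthogroups = 30, n_shared_all = 10,
    n_shared_bacterial = 0, seed = 5))
  tr <- truth_rtp(study$truth, study$truth$condition_ids)
  c_j <- with(study$truth$orthogroups, stats::setNames(c, orthogroup))
  expect_equal(tr, c_j[names(tr)])
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_conditions = 0), "positive integer")
  expect_error(synthetic_config(genes_per_condition = 2.5), "positive integer")
  expect_error(synthetic_config(n_replicates = 1), ">= 2")
  expect_error(synthetic_config(ortholog_coverage = 1.2), "probability")
  expect_error(synthetic_config(conserved_ptr_sd = -1), "non-negative")
  expect_error(synthetic_config(essential_sd_scale = 0), "\\(0, 1\\]")
  expect_error(synthetic_config(essential_noise_scale = 1.5), "\\(0, 1\\]")
  expect_error(synthetic_config(n_shared_all = 500, n_shared_bacterial = 200,
                                n_orthogroups = 600), "exceed")
  expect_error(generate_study(tiny_config(genes_per_condition = 10)),
               "smaller than the orthologous")
})

test_that("generated structure matches the configuration", {
  cfg <- tiny_config(seed = 9)
  study <- generate_study(cfg)
  expect_length(study$tables, cfg$n_conditions)
  for (cond in names(study$tables)) {
    expect_equal(dim(study$tables[[cond]]$mrna$values),
                 c(cfg$genes_per_condition, cfg$n_replicates))
    expect_equal(study$tables[[cond]]$protein$condition_id, cond)
  }
  # shared_all orthogroups cover every condition; single-copy throughout
  conds <- study$truth$condition_ids
  for (og in sprintf("OG%04d", seq_len(cfg$n_shared_all))) {
    expect_equal(og_coverage(study$map, og), conds)
    for (cond in conds) expect_true(og_single_copy(study$map, og, cond))
  }
  # injected outliers respect |c_j| >= magnitude - conserved_ptr_sd
  outl <- subset(study$truth$orthogroups, outlier)
  if (nrow(outl)) {
    expect_true(all(abs(outl$c) >= cfg$outlier_magnitude - cfg$conserved_ptr_sd))
    expect_true(all(sign(outl$c) == outl$outlier_sign))
  }
  # essential lists point at real genes
  for (cond in conds) {
    expect_true(all(study$essential[[cond]] %in%
                      study$tables[[cond]]$mrna$gene_ids))
  }
})

test_that("mRNA-protein correlation falls as conserved ptr spread grows", {
  mean_rho <- function(csd) {
    rhos <- numeric(20)
    for (s in 1:20) {
      study <- generate_study(tiny_config(conserved_ptr_sd = csd, seed = s))
      pair <- preprocess_study(study$tables)[[1]]
      v <- rtpfactor:::paired_values(pair)
      rhos[s] <- spearman(v$r, v$p)$rho
    }
    mean(rhos)
  }
  r <- vapply(c(0.8, 1.5, 2.5), mean_rho, 0)
  expect_true(all(diff(r) < 0))
})

test_that("write_study round-trips through the io readers", {
  dir <- withr::local_tempdir()
  study <- generate_study(tiny_config(seed = 2))
  write_study(study, dir)
  conds <- study$truth$condition_ids
  tab <- read_abundance_table(file.path(dir, "S1_mrna.tsv"), "S1", "mRNA")
  expect_equal(tab$values, study$tables[["S1"]]$mrna$values)
  map <- read_orthogroups(file.path(dir, "Orthogroups.tsv"), conds)
  expect_identical(map$groups, study$map$groups)
  ess <- read_gene_list(file.path(dir, "S1_essential.txt"))
  expect_setequal(as.character(ess), study$essential[["S1"]])
})
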
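# Synthetic multi-condition paired transcriptome/proteome studies with
# known ground truth. The generator emulates the statistical structure the
# downstream analyses assume: log2 mRNA-protein coupling in the moderate
# (rho ~ 0.4-0.65) regime, gene-specific ptr offsets partly conserved
# across conditions, a left-skewed ptr outlier mixture, logistic protein
# dropout giving paired-detection fractions in the 30-78% band, and an
# essential subset with higher abundance, lower variance and tighter
# coupling.

#' Synthetic study configuration
#'
#' All abundance-scale parameters are in log2 units. The defaults describe
#' a nine-condition study (eight bacterial conditions plus one archaeal
#' outgroup) of 2,500 genes per condition and 600 orthogroups, of which 58
#' cover all nine conditions and a further 82 cover the eight bacterial
#' conditions (so 140 orthogroups are shared across the bacteria).
#'
#' @param n_conditions Number of conditions.
#' @param genes_per_condition Genes per condition (orthologous + private).
#' @param n_orthogroups Number of orthogroups.
#' @param ortholog_coverage Probability an unstructured orthogroup is
#'   present in a given condition.
#' @param n_shared_all Orthogroups forced to cover every condition.
#' @param n_shared_bacterial Orthogroups forced to cover every condition
#'   except the last (the archaeal outgroup in the default layout).
#' @param n_replicates Replicates per condition per modality (>= 2).
#' @param mrna_mean,mrna_sd Latent log2 mRNA abundance distribution.
#' @param ortholog_mrna_share Fraction of latent mRNA variance shared
#'   across conditions within an orthogroup (drives cross-condition mRNA
#'   correlation).
#' @param conserved_ptr_sd SD of the per-orthogroup conserved ptr offset
#'   c_j (shared across conditions).
#' @param species_ptr_sd SD of the per-(condition, orthogroup) ptr
#'   deviation d_ij.
#' @param replicate_noise_sd SD of per-replicate mRNA noise.
#' @param measurement_noise_sd SD of per-replicate protein measurement
#'   noise.
#' @param outlier_fraction Probability a (non-essential) orthogroup or
#'   private gene carries an injected extreme ptr offset.
#' @param outlier_magnitude Absolute log2 magnitude of injected offsets.
#' @param outlier_sign_bias Probability an injected outlier is low-ptr
#'   (controls the left skew of the ptr distribution).
#' @param essential_fraction Fraction of genes that are essential.
#' @param essential_mean_shift Upward shift of essential latent mRNA means.
#' @param essential_sd_scale Multiplier in (0, 1] on the latent mRNA SD of
#'   essential genes.
#' @param essential_noise_scale Multiplier in (0, 1] on the ptr offsets and
#'   noise terms of essential genes (tighter mRNA-protein coupling).
#' @param protein_dropout_midpoint Latent log2 protein abundance at which
#'   the per-replicate detection probability is 0.5 (`-Inf` disables
#'   dropout).
#' @param protein_dropout_slope Slope of the logistic detection curve.
#' @param dropout_hetero_sd SD of a per-gene detection propensity added to
#'   the latent protein abundance inside the logistic. Shared across
#'   conditions within an orthogroup (detectability is largely a sequence
#'   property, so it travels with the ortholog), drawn independently for
#'   private genes. Makes detection bimodal per gene and correlated across
#'   conditions, as in real MS data; `0` recovers pure abundance-driven
#'   dropout.
#' @param core_mean_shift Extra latent mRNA mean (log2) for the structured
#'   shared orthogroups (`n_shared_all` + `n_shared_bacterial`), emulating
#'   the high expression of universally conserved housekeeping genes.
#' @param mrna_library_depth Reads per mRNA replicate for Poisson count
#'   sampling; `NA` emits exact linear abundances instead of counts.
#' @param normalize_latents If `TRUE` (default), latent linear abundances
#'   are rescaled so each condition totals 1e6 per modality, with the
#'   per-condition shift folded into the recorded truth. This makes RPM and
#'   total-intensity normalization unit-neutral so recovered conversion
#'   factors are comparable to the truth without an arbitrary per-study
#'   constant.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `synthetic_config` (a named list).
#' @export
synthetic_config <- function(n_conditions = 9,
                             genes_per_condition = 2500,
                             n_orthogroups = 600,
                             ortholog_coverage = 0.55,
                             n_shared_all = 58,
                             n_shared_bacterial = 82,
                             n_replicates = 4,
                             mrna_mean = 7,
                             mrna_sd = 1.3,
                             ortholog_mrna_share = 0.5,
                             conserved_ptr_sd = 1.5,
                             species_ptr_sd = 0.5,
                             replicate_noise_sd = 0.8,
                             measurement_noise_sd = 0.5,
                             outlier_fraction = 0.06,
                             outlier_magnitude = 5,
                             outlier_sign_bias = 0.8,
                             essential_fraction = 0.08,
                             essential_mean_shift = 2,
                             essential_sd_scale = 0.5,
                             essential_noise_scale = 0.5,
                             protein_dropout_midpoint = 6,
                             protein_dropout_slope = 1,
                             dropout_hetero_sd = 32,
                             core_mean_shift = 1.5,
                             mrna_library_depth = 2e6,
                             normalize_latents = TRUE,
                             seed = 1) {
  cfg <- as.list(environment())
  for (f in c("n_conditions", "genes_per_condition", "n_orthogroups",
              "n_replicates", "seed")) {
    assert_that(is_count(cfg[[f]]), "config field '%s' must be a positive integer", f)
  }
  assert_that(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  for (f in c("ortholog_coverage", "outlier_fraction", "outlier_sign_bias",
              "essential_fraction", "ortholog_mrna_share")) {
    assert_that(is_prob(cfg[[f]]), "config field '%s' must be a probability in [0, 1]", f)
  }
  for (f in c("mrna_sd", "conserved_ptr_sd", "species_ptr_sd",
              "replicate_noise_sd", "measurement_noise_sd",
              "outlier_magnitude")) {
    assert_that(is_nonneg(cfg[[f]]), "config field '%s' must be a non-negative number", f)
  }
  for (f in c("essential_sd_scale", "essential_noise_scale")) {
    v <- cfg[[f]]
    assert_that(is.numeric(v) && length(v) == 1L && v > 0 && v <= 1,
                "config field '%s' must be in (0, 1]", f)
  }
  assert_that(length(cfg$n_shared_all) == 1L && cfg$n_shared_all >= 0 &&
                length(cfg$n_shared_bacterial) == 1L && cfg$n_shared_bacterial >= 0 &&
                cfg$n_shared_all + cfg$n_shared_bacterial <= cfg$n_orthogroups,
              "n_shared_all + n_shared_bacterial must not exceed n_orthogroups")
  assert_that(is.na(cfg$mrna_library_depth) || is_count(cfg$mrna_library_depth),
              "mrna_library_depth must be NA or a positive integer")
  assert_that(is_nonneg(cfg$dropout_hetero_sd),
              "dropout_hetero_sd must be a non-negative number")
  assert_that(is.numeric(cfg$core_mean_shift) && is.finite(cfg$core_mean_shift),
              "core_mean_shift must be a finite number")
  structure(cfg, class = "synthetic_config")
}

#' Named synthetic presets
#'
#' `"study"` is the nine-condition default layout (eight bacterial
#' conditions plus an archaeal outgroup). `"bacteria"` is the
#' eight-condition bacterial subset with 140 universally shared
#' orthogroups, the layout used for conversion-factor recovery
#' experiments. Extra arguments override preset fields.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("study", "bacteria"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    study = list(),
    bacteria = list(n_conditions = 8, n_shared_all = 140, n_shared_bacterial = 0))
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

#' Generate a synthetic paired transcriptome/proteome study
#'
#' Generative model, all on the log2 scale. Latent mRNA means:
#' `mu_ij = m_j + a_ij` for orthologous genes (shared component `m_j`) and
#' an independent draw for private genes; essential genes are shifted up by
#' `essential_mean_shift` with SD scaled by `essential_sd_scale`. Protein
#' latent: `lambda_ij = mu_ij + c_j + d_ij` (orthologs; private genes use a
#' one-off offset with the pooled SD). Injected outliers add
#' `+/- outlier_magnitude` to the offset, with sign low with probability
#' `outlier_sign_bias`. Replicates: mRNA `mu + eta` then (optionally)
#' Poisson count sampling at the configured library depth; protein
#' `lambda + eps` on the linear scale with per-replicate logistic dropout
#' in the latent protein abundance.
#'
#' @param config A `synthetic_config`.
#' @return List with `tables` (per condition: list with `mrna` and
#'   `protein` `abundance_table`s), `map` (an `ortholog_map`), `essential`
#'   (named list of per-condition essential gene id vectors), and `truth`
#'   (a `synthetic_truth`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  C <- cfg$n_conditions
  G <- cfg$genes_per_condition
  K <- cfg$n_orthogroups
  R <- cfg$n_replicates
  conds <- sprintf("S%d", seq_len(C))
  ogs <- sprintf("OG%04d", seq_len(K))

  # --- coverage ------------------------------------------------------------
  coverage <- matrix(FALSE, K, C, dimnames = list(ogs, conds))
  idx <- 0L
  if (cfg$n_shared_all > 0) {
    coverage[seq_len(cfg$n_shared_all), ] <- TRUE
    idx <- cfg$n_shared_all
  }
  if (cfg$n_shared_bacterial > 0) {
    rows <- idx + seq_len(cfg$n_shared_bacterial)
    coverage[rows, seq_len(max(C - 1L, 1L))] <- TRUE
    idx <- idx + cfg$n_shared_bacterial
  }
  if (idx < K) {
    free <- (idx + 1L):K
    coverage[free, ] <- matrix(stats::runif(length(free) * C) < cfg$ortholog_coverage,
                               length(free), C)
    none <- free[rowSums(coverage[free, , drop = FALSE]) == 0L]
    if (length(none)) {
      coverage[cbind(none, sample.int(C, length(none), replace = TRUE))] <- TRUE
    }
  }
  n_ortho_per_cond <- colSums(coverage)
  assert_that(all(n_ortho_per_cond <= G),
              "genes_per_condition (%d) is smaller than the orthologous gene count (max %d)",
              G, max(n_ortho_per_cond))

  # --- orthogroup-level truth ----------------------------------------------
  ess_og <- stats::runif(K) < cfg$essential_fraction
  out_og <- !ess_og & stats::runif(K) < cfg$outlier_fraction
  out_sign <- ifelse(stats::runif(K) < cfg$outlier_sign_bias, -1, 1)
  out_sign[!out_og] <- NA_real_
  c_sd <- ifelse(ess_og, cfg$conserved_ptr_sd * cfg$essential_noise_scale,
                 cfg$conserved_ptr_sd)
  c_j <- stats::rnorm(K, 0, c_sd)
  if (any(out_og)) {
    # injected offsets keep |c_j| >= magnitude - conserved_ptr_sd by
    # clamping the perturbation, while recording the realized value
    pert <- clamp(stats::rnorm(sum(out_og), 0, cfg$conserved_ptr_sd),
                  -cfg$conserved_ptr_sd, cfg$conserved_ptr_sd)
    c_j[out_og] <- out_sign[out_og] * cfg$outlier_magnitude + pert
  }
  share <- cfg$ortholog_mrna_share
  m_sd <- ifelse(ess_og, cfg$mrna_sd * cfg$essential_sd_scale, cfg$mrna_sd)
  m_j <- stats::rnorm(K, cfg$mrna_mean + ifelse(ess_og, cfg$essential_mean_shift, 0),
                      m_sd * sqrt(share))
  n_core <- cfg$n_shared_all + cfg$n_shared_bacterial
  if (n_core > 0) {
    m_j[seq_len(n_core)] <- m_j[seq_len(n_core)] + cfg$core_mean_shift
  }
  # detection propensity travels with the orthogroup (sequence-determined)
  u_og <- stats::rnorm(K, 0, cfg$dropout_hetero_sd)
  d_scale <- ifelse(ess_og, cfg$essential_noise_scale, 1)
  d_mat <- matrix(stats::rnorm(K * C, 0, cfg$species_ptr_sd), K, C,
                  dimnames = list(ogs, conds)) * d_scale
  a_mat <- matrix(stats::rnorm(K * C, 0, 1), K, C) * (m_sd * sqrt(1 - share))

  # --- per-condition assembly ----------------------------------------------
  groups <- lapply(ogs, function(og) list())
  names(groups) <- ogs
  tables <- vector("list", C)
  essential_lists <- vector("list", C)
  latent_mrna <- vector("list", C)
  private_offsets <- vector("list", C)
  outlier_rows <- list()
  d_truth <- matrix(NA_real_, K, C, dimnames = list(ogs, conds))
  priv_sd <- sqrt(cfg$conserved_ptr_sd^2 + cfg$species_ptr_sd^2)

  for (ci in seq_len(C)) {
    cond <- conds[ci]
    present <- which(coverage[, ci])
    n_priv <- G - length(present)
    og_gene_ids <- sprintf("%s_%s", cond, ogs[present])
    priv_ids <- sprintf("%s_p%04d", cond, seq_len(n_priv))
    gene_ids <- c(og_gene_ids, priv_ids)
    for (k in seq_along(present)) {
      groups[[ogs[present[k]]]][[cond]] <- og_gene_ids[k]
    }

    # private-gene truth
    ess_priv <- stats::runif(n_priv) < cfg$essential_fraction
    out_priv <- !ess_priv & stats::runif(n_priv) < cfg$outlier_fraction
    sign_priv <- ifelse(stats::runif(n_priv) < cfg$outlier_sign_bias, -1, 1)
    b_sd <- ifelse(ess_priv, priv_sd * cfg$essential_noise_scale, priv_sd)
    b_g <- stats::rnorm(n_priv, 0, b_sd)
    if (any(out_priv)) {
      pert <- clamp(stats::rnorm(sum(out_priv), 0, cfg$conserved_ptr_sd),
                    -cfg$conserved_ptr_sd, cfg$conserved_ptr_sd)
      b_g[out_priv] <- sign_priv[out_priv] * cfg$outlier_magnitude + pert
    }
    mu_priv_mean <- cfg$mrna_mean + ifelse(ess_priv, cfg$essential_mean_shift, 0)
    mu_priv_sd <- ifelse(ess_priv, cfg$mrna_sd * cfg$essential_sd_scale, cfg$mrna_sd)
    mu_priv <- stats::rnorm(n_priv, mu_priv_mean, mu_priv_sd)

    mu <- c(m_j[present] + a_mat[present, ci], mu_priv)
    offset <- c(c_j[present] + d_mat[present, ci], b_g)
    ess_gene <- c(ess_og[present], ess_priv)
    noise_scale <- ifelse(ess_gene, cfg$essential_noise_scale, 1)

    # latent rescaling: make each condition's linear totals 1e6 so RPM /
    # total-intensity normalization is unit-neutral; fold the shifts into
    # the recorded truth
    if (cfg$normalize_latents) {
      t_i <- log2(1e6 / sum(2^mu))
      mu <- mu + t_i
      s_i <- log2(1e6 / sum(2^(mu + offset)))
      offset <- offset + s_i
    }
    lambda <- mu + offset
    d_truth[present, ci] <- offset[seq_along(present)] - c_j[present]

    # replicates
    eta <- matrix(stats::rnorm(G * R, 0, cfg$replicate_noise_sd), G, R) *
      noise_scale
    mrna_lin <- 2^(mu + eta)
    if (!is.na(cfg$mrna_library_depth)) {
      mrna_vals <- vapply(seq_len(R), function(r) {
        lam <- cfg$mrna_library_depth * mrna_lin[, r] / sum(mrna_lin[, r])
        as.numeric(stats::rpois(G, lam))
      }, numeric(G))
    } else {
      mrna_vals <- mrna_lin
    }
    eps <- matrix(stats::rnorm(G * R, 0, cfg$measurement_noise_sd), G, R) *
      noise_scale
    prot_lin <- 2^(lambda + eps)
    if (is.finite(cfg$protein_dropout_midpoint)) {
      u_priv <- stats::rnorm(n_priv, 0, cfg$dropout_hetero_sd)
      u <- c(u_og[present], u_priv)
      p_det <- stats::plogis(cfg$protein_dropout_slope *
                               (lambda + u - cfg$protein_dropout_midpoint))
      detected <- matrix(stats::runif(G * R), G, R) < p_det
      prot_lin[!detected] <- 0
    }

    tables[[ci]] <- list(
      mrna = abundance_table(cond, "mRNA", gene_ids, mrna_vals),
      protein = abundance_table(cond, "protein", gene_ids, prot_lin))
    essential_lists[[ci]] <- gene_ids[ess_gene]
    latent_mrna[[ci]] <- stats::setNames(mu, gene_ids)
    private_offsets[[ci]] <- stats::setNames(b_g, priv_ids)

    out_here <- c(out_og[present], out_priv)
    if (any(out_here)) {
      sgn <- c(out_sign[present], sign_priv)
      og_here <- c(ogs[present], rep(NA_character_, n_priv))
      outlier_rows[[cond]] <- data.frame(
        condition = cond, gene_id = gene_ids[out_here],
        orthogroup = og_here[out_here], sign = sgn[out_here],
        stringsAsFactors = FALSE)
    }
  }
  names(tables) <- conds
  names(essential_lists) <- conds
  names(latent_mrna) <- conds
  names(private_offsets) <- conds

  truth <- structure(list(
    orthogroups = data.frame(orthogroup = ogs, c = c_j, essential = ess_og,
                             outlier = out_og, outlier_sign = out_sign,
                             stringsAsFactors = FALSE),
    d = d_truth,
    latent_mrna = latent_mrna,
    private_offsets = private_offsets,
    injected_outliers = if (length(outlier_rows)) {
      out <- do.call(rbind, outlier_rows); row.names(out) <- NULL; out
    } else {
      data.frame(condition = character(0), gene_id = character(0),
                 orthogroup = character(0), sign = numeric(0))
    },
    essential = essential_lists,
    condition_ids = conds,
    config = cfg), class = "synthetic_truth")

  list(tables = tables,
       map = ortholog_map(groups, conds),
       essential = essential_lists,
       truth = truth)
}

#' Ground-truth conversion factors
#'
#' The expected RTP conversion factor of each orthogroup covered by every
#' condition in `condition_subset`: the conserved offset `c_j` plus the
#' mean over the subset of the per-condition deviations `d_ij`.
#'
#' @param truth A `synthetic_truth`.
#' @param condition_subset Non-empty character vector of condition ids.
#' @return Named numeric vector, orthogroup -> expected factor.
#' @export
truth_rtp <- function(truth, condition_subset) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_that(length(condition_subset) >= 1L, "condition subset is empty")
  unknown <- setdiff(condition_subset, truth$condition_ids)
  assert_that(length(unknown) == 0L, "unknown condition id(s): %s",
              paste(unknown, collapse = ", "))
  d <- truth$d[, condition_subset, drop = FALSE]
  covered <- rowSums(is.na(d)) == 0L
  c_j <- stats::setNames(truth$orthogroups$c, truth$orthogroups$orthogroup)
  c_j[covered] + rowMeans(d[covered, , drop = FALSE])
}

#' Write a generated study to disk
#'
#' Emits per-condition mRNA/protein abundance TSVs, an Orthogroups.tsv,
#' per-condition essential gene lists, truth tables (orthogroup offsets and
#' injected outliers), and the configuration as JSON.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cond in names(study$tables)) {
    for (mod in c("mrna", "protein")) {
      p <- file.path(dir, sprintf("%s_%s.tsv", cond, mod))
      write_abundance_table(study$tables[[cond]][[mod]], p)
      paths[[sprintf("%s_%s", cond, mod)]] <- p
    }
    p <- file.path(dir, sprintf("%s_essential.txt", cond))
    write_gene_list(study$essential[[cond]], p)
    paths[[sprintf("%s_essential", cond)]] <- p
  }
  paths$orthogroups <- file.path(dir, "Orthogroups.tsv")
  write_orthogroups(study$map, paths$orthogroups)
  paths$truth_orthogroups <- file.path(dir, "truth_orthogroups.tsv")
  utils::write.table(study$truth$orthogroups, paths$truth_orthogroups,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth_outliers <- file.path(dir, "truth_outliers.tsv")
  utils::write.table(study$truth$injected_outliers, paths$truth_outliers,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$config <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(study$truth$config), paths$config,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
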
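# End-to-end orchestration: config-driven runs over synthetic or user
# data, stage TSV reports, a summary JSON, and a reproducibility manifest.

default_analysis <- function() {
  list(hotspot_threshold = 1e5,
       min_protein_replicates = NULL,
       outlier_clip = 2,
       top_k = 15,
       ranking_conditions = NULL,   # default: all but the last condition
       loo = TRUE,
       null_draws = 0,
       null_target = NULL,
       gene_scope = NULL)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), "config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  assert_that(is.list(config), "config must be a list or a JSON file path")
  assert_that(!is.null(config$simulate) || !is.null(config$inputs),
              "config needs either a 'simulate' or an 'inputs' section")
  config$seed <- config$seed %||% 1L
  config$analysis <- utils::modifyList(default_analysis(),
                                       config$analysis %||% list())
  config
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- sim$seed %||% derive_seed(config$seed, "simulate")
    cfg <- do.call(synthetic_config, sim)
    study <- generate_study(cfg)
    return(list(tables = study$tables, map = study$map,
                essential = study$essential, truth = study$truth,
                checksums = list(simulate_config = fnv1a(jsonlite::toJSON(unclass(cfg))))))
  }
  inp <- config$inputs
  conds <- vapply(inp$conditions, `[[`, "", "id")
  files <- unlist(lapply(inp$conditions, function(x) c(x$mrna, x$protein)))
  files <- c(files, inp$orthogroups, unlist(inp$essential))
  missing <- files[!file.exists(files)]
  assert_that(length(missing) == 0L, "missing input file(s): %s",
              paste(missing, collapse = ", "))
  tables <- lapply(inp$conditions, function(x) {
    list(mrna = read_abundance_table(x$mrna, x$id, "mRNA"),
         protein = read_abundance_table(x$protein, x$id, "protein"))
  })
  names(tables) <- conds
  map <- read_orthogroups(inp$orthogroups, conds)
  essential <- NULL
  if (!is.null(inp$essential)) {
    essential <- lapply(inp$essential, read_gene_list)
  }
  checksums <- lapply(files, function(f) fnv1a(readLines(f, warn = FALSE)))
  names(checksums) <- files
  list(tables = tables, map = map, essential = essential, truth = NULL,
       checksums = checksums)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (hotspot filter, RPM, protein
#' scaling, detection), per-condition mRNA-protein correlation, pairwise
#' ortholog correlation matrices with the protein-vs-mRNA conservation
#' test, the essential-gene contrast (skipped when no essential lists are
#' configured), ptr-outlier detection with the conserved-ortholog ranking,
#' and RTP conversion factors with leave-one-out validation and (when
#' `null_draws > 0`) the randomized null. Writes one TSV per stage, a
#' `summary.json` whose numbers are all taken from those TSVs, and a
#' `manifest.json` recording config hash, seeds and input checksums.
#'
#' @param config Path to a JSON config file, or an equivalent list. Must
#'   contain either `simulate` (arguments for [synthetic_config()]) or
#'   `inputs` (`conditions` with `id`/`mrna`/`protein` paths,
#'   `orthogroups`, optional `essential`), plus optional `seed` and
#'   `analysis` overrides.
#' @param outdir Output directory.
#' @return Invisibly, the manifest (also written as JSON).
#' @export
run_pipeline <- function(config, outdir) {
  config <- read_pipeline_config(config)
  an <- config$analysis
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rtpfactor")),
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    seed = config$seed,
    seed_registry = list(),
    stages = list())

  inputs <- load_inputs(config)
  manifest$input_checksums <- inputs$checksums
  conds <- names(inputs$tables)

  # --- preprocess ----------------------------------------------------------
  pairs <- preprocess_study(inputs$tables,
                            hotspot_threshold = an$hotspot_threshold,
                            min_protein_replicates = an$min_protein_replicates)
  detect <- do.call(rbind, lapply(conds, function(cond) {
    pair <- pairs[[cond]]
    total <- nrow(inputs$tables[[cond]]$mrna$values)
    data.frame(condition = cond, genes_total = total,
               mrna_detected = nrow(pair$mrna),
               protein_detected = nrow(pair$protein),
               paired = length(pair$paired_ids),
               paired_fraction = length(pair$paired_ids) / total,
               hotspot_removed = length(attr(pair, "hotspot_removed")),
               stringsAsFactors = FALSE)
  }))
  manifest$stages$preprocess <- write_tsv(detect, file.path(outdir, "detection.tsv"))

  # --- correlation ---------------------------------------------------------
  corr <- do.call(rbind, lapply(conds, function(cond) {
    v <- paired_values(pairs[[cond]])
    sp <- spearman(v$r, v$p)
    fit <- fit_r_squared(v$r, v$p)
    data.frame(condition = cond, n = sp$n, rho = sp$rho,
               r_squared = fit$r_squared, stringsAsFactors = FALSE)
  }))
  manifest$stages$correlation <- write_tsv(corr, file.path(outdir, "correlation.tsv"))

  pm_m <- pairwise_ortholog_matrix(pairs, inputs$map, "mRNA")
  pm_p <- pairwise_ortholog_matrix(pairs, inputs$map, "protein")
  cons <- compare_protein_vs_mrna_conservation(pm_m, pm_p)
  write_matrix <- function(m, path) {
    df <- data.frame(condition = rownames(m), m, check.names = FALSE)
    write_tsv(df, path)
  }
  manifest$stages$pairwise <- c(
    write_matrix(pm_m$rho, file.path(outdir, "pairwise_rho_mrna.tsv")),
    write_matrix(pm_p$rho, file.path(outdir, "pairwise_rho_protein.tsv")),
    write_matrix(pm_m$n, file.path(outdir, "pairwise_n.tsv")))

  # --- essential (optional) ------------------------------------------------
  essential_summary <- NULL
  if (!is.null(inputs$essential) && length(inputs$essential) > 0) {
    essential_summary <- do.call(rbind, lapply(intersect(conds, names(inputs$essential)),
      function(cond) {
        part <- partition_by_essentiality(pairs[[cond]], inputs$essential[[cond]])
        gc <- abundance_sd_contrast(pairs[[cond]], part)
        data.frame(condition = cond, n_essential = gc$n_essential,
                   n_non_essential = gc$n_non_essential,
                   rho_e = gc$rho_e, rho_ne = gc$rho_ne,
                   p_abundance_mrna = gc$summary$p_value[
                     gc$summary$modality == "mRNA" & gc$summary$metric == "abundance"],
                   p_sd_mrna = gc$summary$p_value[
                     gc$summary$modality == "mRNA" & gc$summary$metric == "sd"],
                   p_abundance_protein = gc$summary$p_value[
                     gc$summary$modality == "protein" & gc$summary$metric == "abundance"],
                   p_sd_protein = gc$summary$p_value[
                     gc$summary$modality == "protein" & gc$summary$metric == "sd"],
                   stringsAsFactors = FALSE)
      }))
    manifest$stages$essential <- write_tsv(essential_summary,
                                           file.path(outdir, "essential.tsv"))
  } else {
    manifest$stages$essential <- "skipped (no essential lists configured)"
  }

  # --- outliers ------------------------------------------------------------
  records <- lapply(conds, function(cond) {
    model <- fit_ptr_regression(pairs[[cond]])
    standardized_residuals(model, pairs[[cond]], inputs$map)
  })
  names(records) <- conds
  counts <- count_outlier_classes(records)
  manifest$stages$outlier_counts <- write_tsv(counts,
                                              file.path(outdir, "outlier_counts.tsv"))
  rank_conds <- an$ranking_conditions %||%
    (if (length(conds) > 2) conds[-length(conds)] else conds)
  ranking <- tryCatch(
    conserved_ranking(records, inputs$map, rank_conds,
                      clip = an$outlier_clip, k = an$top_k),
    error = function(e) NULL)
  if (!is.null(ranking)) {
    zdf <- data.frame(orthogroup = rownames(ranking$z),
                      mean_z = as.numeric(ranking$mean_z), ranking$z,
                      check.names = FALSE)
    manifest$stages$outlier_ranking <- write_tsv(zdf,
                                                 file.path(outdir, "outlier_ranking.tsv"))
  }

  # --- rtp / leave-one-out / null ------------------------------------------
  loo <- NULL
  if (isTRUE(an$loo) && length(conds) >= 2) {
    scope <- an$gene_scope
    loo <- leave_one_out(pairs, inputs$map, gene_scope = scope)
    manifest$stages$loo <- write_tsv(loo$results, file.path(outdir, "loo.tsv"))
  }
  null_df <- NULL
  if ((an$null_draws %||% 0) > 0) {
    target <- an$null_target %||% conds[length(conds)]
    nseed <- derive_seed(config$seed, "null")
    manifest$seed_registry$null <- nseed
    null_df <- randomized_rtp(pairs[setdiff(conds, target)], pairs[[target]],
                              inputs$map, gene_scope = an$gene_scope,
                              n_draws = an$null_draws, seed = nseed)
    manifest$stages$null <- write_tsv(null_df, file.path(outdir, "null.tsv"))
  }

  # --- summary -------------------------------------------------------------
  summary <- list(
    conditions = conds,
    detection = detect,
    correlation = corr,
    conservation = list(wins = cons$wins, n_pairs = cons$n_pairs,
                        p_value = cons$p_value),
    outlier_counts = counts,
    essential = essential_summary,
    loo = if (!is.null(loo)) list(results = loo$results, p_value = loo$p_value),
    null = if (!is.null(null_df)) list(mean_delta = mean(null_df$delta),
                                       q95_delta = unname(stats::quantile(null_df$delta, 0.95))))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", na = "null")
  manifest$stages$summary <- file.path(outdir, "summary.json")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
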
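# Normalization and detection filtering: raw counts -> RPM, protein
# intensities -> cross-condition median scaling, then aggregation to
# per-condition log2 expression profiles (R_ij for mRNA, P_ij for protein).

#' Reads-per-million normalization
#'
#' Scales each replicate column of an mRNA count table so that its total is
#' one million. Depth-invariant: replicates with different sequencing depth
#' but identical proportions yield identical RPM columns.
#'
#' @param table An `abundance_table` with modality `"mRNA"`.
#' @return A normalized `abundance_table`.
#' @export
rpm_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  assert_that(table$modality == "mRNA",
              "rpm_normalize expects an mRNA table, got '%s'", table$modality)
  totals <- colSums(table$values)
  zero <- which(totals <= 0)
  assert_that(length(zero) == 0L,
              "rpm_normalize: replicate '%s' of '%s' has zero total",
              table$replicate_ids[zero[1]], table$condition_id)
  vals <- sweep(table$values, 2, totals, "/") * 1e6
  abundance_table(table$condition_id, "mRNA", table$gene_ids, vals,
                  table$replicate_ids)
}

#' Remove PCR hotspot genes
#'
#' Drops genes whose mean raw read count across replicates is strictly
#' greater than `threshold` (default 0.1 million reads), the signature of
#' PCR hotspots. Must be applied to raw counts, before RPM normalization.
#'
#' @param table An `abundance_table` with modality `"mRNA"` (raw counts).
#' @param threshold Mean-count cutoff; strict inequality.
#' @return A list with elements `table` (filtered `abundance_table`) and
#'   `removed` (character vector of removed gene ids).
#' @export
hotspot_filter <- function(table, threshold = 1e5) {
  stopifnot(inherits(table, "abundance_table"))
  means <- rowMeans(table$values)
  removed <- table$gene_ids[means > threshold]
  keep <- !(table$gene_ids %in% removed)
  out <- abundance_table(table$condition_id, table$modality,
                         table$gene_ids[keep],
                         table$values[keep, , drop = FALSE],
                         table$replicate_ids)
  list(table = out, removed = removed)
}

#' Species-specific protein scaling
#'
#' Computes, for each condition, the ratio between its total protein
#' abundance and the median total across all conditions, and divides by that
#' factor so every condition's total equals the original median. This makes
#' reporter-ion intensities from different MS runs directly comparable.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param tables List of `abundance_table` objects with modality `"protein"`.
#' @return List of scaled tables, with attribute `scale_factors` (named
#'   numeric vector of the factors applied).
#' @export
protein_scale <- function(tables) {
  assert_that(length(tables) >= 1L, "protein_scale: need at least one table")
  for (t in tables) {
    stopifnot(inherits(t, "abundance_table"))
    assert_that(t$modality == "protein",
                "protein_scale expects protein tables, got '%s' for '%s'",
                t$modality, t$condition_id)
  }
  totals <- vapply(tables, function(t) sum(t$values), 0)
  zero <- which(totals <= 0)
  assert_that(length(zero) == 0L, "protein_scale: condition '%s' has zero total",
              tables[[zero[1]]]$condition_id)
  med <- stats::median(totals)
  factors <- totals / med
  out <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    abundance_table(t$condition_id, "protein", t$gene_ids,
                    t$values / factors[i], t$replicate_ids)
  })
  names(out) <- vapply(tables, function(t) t$condition_id, "")
  names(factors) <- names(out)
  attr(out, "scale_factors") <- factors
  out
}

#' Aggregate replicates and apply detection filters
#'
#' Produces the per-condition log2 expression profiles used by all
#' downstream analyses. A protein is detected iff its abundance is positive
#' in at least `min_protein_replicates` replicates (default: all of them,
#' the four-replicate rule for TMT data); an mRNA is detected iff its mean
#' normalized abundance is positive. The per-gene value is
#' log2(mean across replicates of the normalized linear abundance); the
#' per-gene SD is the standard deviation across replicates of
#' log2(abundance), over replicates with positive abundance.
#'
#' @param mrna Normalized mRNA `abundance_table`.
#' @param protein Normalized protein `abundance_table` (same condition).
#' @param min_protein_replicates Detection rule for proteins; `NULL` means
#'   "all replicates".
#' @return A `profile_pair`: list with `condition_id`, data frames `mrna`
#'   and `protein` (columns `gene_id`, `value`, `sd`; detected genes only),
#'   and `paired_ids` (genes detected in both modalities).
#' @export
aggregate_and_filter <- function(mrna, protein, min_protein_replicates = NULL) {
  stopifnot(inherits(mrna, "abundance_table"), inherits(protein, "abundance_table"))
  assert_that(identical(mrna$condition_id, protein$condition_id),
              "condition mismatch: mRNA '%s' vs protein '%s'",
              mrna$condition_id, protein$condition_id)
  min_rep <- min_protein_replicates %||% ncol(protein$values)
  assert_that(is_count(min_rep) && min_rep <= ncol(protein$values),
              "min_protein_replicates must be a count <= %d", ncol(protein$values))

  summarize <- function(values, gene_ids, detected) {
    vals <- values[detected, , drop = FALSE]
    mean_lin <- rowMeans(vals)
    sds <- apply(vals, 1, function(v) {
      v <- v[v > 0]
      if (length(v) >= 2L) stats::sd(log2(v)) else NA_real_
    })
    data.frame(gene_id = gene_ids[detected], value = log2(mean_lin),
               sd = sds, stringsAsFactors = FALSE, row.names = NULL)
  }

  mrna_det <- rowMeans(mrna$values) > 0
  prot_det <- rowSums(protein$values > 0) >= min_rep
  mprof <- summarize(mrna$values, mrna$gene_ids, mrna_det)
  pprof <- summarize(protein$values, protein$gene_ids, prot_det)
  profile_pair(mrna$condition_id, mprof, pprof)
}

#' Construct a profile pair from log2 expression profiles
#'
#' Useful when log2-normalized values are already available (e.g. from an
#' external pipeline) and the abundance-table route is unnecessary.
#'
#' @param condition_id Condition label.
#' @param mrna,protein Data frames with columns `gene_id` and `value`
#'   (log2 normalized abundance) and optionally `sd`; detected genes only.
#' @return A `profile_pair`.
#' @export
profile_pair <- function(condition_id, mrna, protein) {
  for (df in list(mrna, protein)) {
    assert_that(all(c("gene_id", "value") %in% colnames(df)),
                "profiles need columns gene_id and value")
    assert_that(all(is.finite(df$value)),
                "profile for '%s' has non-finite log2 values", condition_id)
  }
  if (is.null(mrna$sd)) mrna$sd <- NA_real_
  if (is.null(protein$sd)) protein$sd <- NA_real_
  structure(list(condition_id = condition_id,
                 mrna = mrna[, c("gene_id", "value", "sd")],
                 protein = protein[, c("gene_id", "value", "sd")],
                 paired_ids = intersect(mrna$gene_id, protein$gene_id)),
            class = "profile_pair")
}

#' @export
print.profile_pair <- function(x, ...) {
  cat(sprintf("<profile_pair> %s: %d mRNA, %d protein, %d paired genes\n",
              x$condition_id, nrow(x$mrna), nrow(x$protein),
              length(x$paired_ids)))
  invisible(x)
}

# Named log2 value vectors for the paired gene set (internal).
paired_values <- function(pair, genes = pair$paired_ids) {
  r <- stats::setNames(pair$mrna$value, pair$mrna$gene_id)[genes]
  p <- stats::setNames(pair$protein$value, pair$protein$gene_id)[genes]
  list(r = r, p = p)
}

#' Full preprocessing for one condition
#'
#' Convenience wrapper: hotspot-filters and RPM-normalizes the raw mRNA
#' counts, then aggregates both modalities with the detection rules.
#' Protein tables are assumed already scaled (see [protein_scale()], which
#' operates across conditions).
#'
#' @param mrna_raw Raw mRNA count `abundance_table`.
#' @param protein_scaled Scaled protein `abundance_table`.
#' @param hotspot_threshold Passed to [hotspot_filter()].
#' @param min_protein_replicates Passed to [aggregate_and_filter()].
#' @return A `profile_pair` with attribute `hotspot_removed`.
#' @export
preprocess_condition <- function(mrna_raw, protein_scaled,
                                 hotspot_threshold = 1e5,
                                 min_protein_replicates = NULL) {
  hs <- hotspot_filter(mrna_raw, hotspot_threshold)
  norm <- rpm_normalize(hs$table)
  pair <- aggregate_and_filter(norm, protein_scaled, min_protein_replicates)
  attr(pair, "hotspot_removed") <- hs$removed
  pair
}

#' Preprocess a whole study
#'
#' Applies cross-condition protein scaling, then per-condition hotspot
#' filtering, RPM normalization and detection filtering.
#'
#' @param tables List (one element per condition) of lists with components
#'   `mrna` and `protein` (`abundance_table`s), as emitted by
#'   [generate_study()].
#' @inheritParams preprocess_condition
#' @return Named list of `profile_pair` objects keyed by condition id.
#' @export
preprocess_study <- function(tables, hotspot_threshold = 1e5,
                             min_protein_replicates = NULL) {
  prot <- protein_scale(lapply(tables, `[[`, "protein"))
  pairs <- lapply(seq_along(tables), function(i) {
    preprocess_condition(tables[[i]]$mrna, prot[[i]],
                         hotspot_threshold, min_protein_replicates)
  })
  names(pairs) <- vapply(prot, function(t) t$condition_id, "")
  pairs
}
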
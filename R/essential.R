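# Essential vs non-essential gene contrasts: abundance and replicate-SD
# distributions (rank-sum tested), correlation split rho_E vs rho_NE, and
# an expression-matched resampling control showing the elevated essential
# correlation is not an artifact of expression level.

#' Partition the paired gene set by essentiality
#'
#' @param pair A `profile_pair`.
#' @param essential_ids Character vector of essential gene ids (e.g. from
#'   transposon-sequencing studies, via [read_gene_list()]).
#' @return List with `essential` and `non_essential` gene id vectors
#'   (partitioning `pair$paired_ids`) and `dropped` (listed essential ids
#'   absent from the paired set).
#' @export
partition_by_essentiality <- function(pair, essential_ids) {
  stopifnot(inherits(pair, "profile_pair"))
  ess <- intersect(pair$paired_ids, essential_ids)
  non <- setdiff(pair$paired_ids, ess)
  if (length(ess) == 0L) {
    warning("no essential genes found in the paired set of '",
            pair$condition_id, "'")
  }
  if (length(non) == 0L) {
    warning("essential list covers every paired gene of '",
            pair$condition_id, "'; non-essential set is empty")
  }
  list(essential = ess, non_essential = non,
       dropped = setdiff(essential_ids, ess))
}

# Rank-sum p-value: exact when min group size <= 10 (per the small-sample
# convention), normal approximation with continuity correction otherwise.
rank_sum_p <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  exact <- min(length(a), length(b)) <= 10L
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Abundance and replicate-SD contrast between essential and non-essential genes
#'
#' Two-sided Wilcoxon rank-sum tests of the log2 abundance and of the
#' per-gene replicate SD, per modality, together with the Spearman
#' mRNA-protein correlation within each group.
#'
#' @param pair A `profile_pair`.
#' @param partition Result of [partition_by_essentiality()].
#' @return A `group_contrast`: list with `summary` (data frame: modality,
#'   metric, group sizes, medians, rank-sum p), `rho_e`, `rho_ne`
#'   (`NA` when a group is too small or degenerate).
#' @export
abundance_sd_contrast <- function(pair, partition) {
  stopifnot(inherits(pair, "profile_pair"))
  ess <- partition$essential
  non <- partition$non_essential
  rows <- list()
  for (mod in c("mRNA", "protein")) {
    prof <- if (mod == "mRNA") pair$mrna else pair$protein
    val <- stats::setNames(prof$value, prof$gene_id)
    sdv <- stats::setNames(prof$sd, prof$gene_id)
    for (metric in c("abundance", "sd")) {
      v <- if (metric == "abundance") val else sdv
      a <- v[ess]; a <- a[is.finite(a)]
      b <- v[non]; b <- b[is.finite(b)]
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, metric = metric,
        n_essential = length(a), n_non_essential = length(b),
        median_essential = if (length(a)) stats::median(a) else NA_real_,
        median_non_essential = if (length(b)) stats::median(b) else NA_real_,
        p_value = rank_sum_p(a, b), stringsAsFactors = FALSE)
    }
  }
  safe_rho <- function(genes) {
    if (length(genes) < 3L) return(NA_real_)
    v <- paired_values(pair, genes)
    tryCatch(spearman(v$r, v$p)$rho, error = function(e) NA_real_)
  }
  structure(list(summary = do.call(rbind, rows),
                 rho_e = safe_rho(ess), rho_ne = safe_rho(non),
                 n_essential = length(ess), n_non_essential = length(non)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %d essential vs %d non-essential; rho_E = %.3f, rho_NE = %.3f\n",
              x$n_essential, x$n_non_essential, x$rho_e, x$rho_ne))
  print(x$summary)
  invisible(x)
}

#' One-dimensional histogram summary with an overflow bin
#'
#' Fixed-width binning used for abundance and SD distributions; values
#' above `clip_max` are accumulated into the final bin rather than widening
#' the axis.
#'
#' @param values Numeric vector.
#' @param bin_size Positive bin width.
#' @param clip_max Optional upper clip; values beyond it land in the last
#'   bin.
#' @param origin Left edge of the first bin (default: floor of the minimum
#'   in units of `bin_size`).
#' @return Data frame with columns `left_edge` and `count`; counts sum to
#'   `length(values)`.
#' @export
histogram_summary <- function(values, bin_size, clip_max = NULL, origin = NULL) {
  assert_that(is.numeric(bin_size) && length(bin_size) == 1L && bin_size > 0,
              "bin_size must be a positive scalar")
  values <- values[is.finite(values)]
  if (!is.null(clip_max)) values <- pmin(values, clip_max)
  if (length(values) == 0L) {
    return(data.frame(left_edge = numeric(0), count = integer(0)))
  }
  origin <- origin %||% (floor(min(values) / bin_size) * bin_size)
  idx <- pmax(floor((values - origin) / bin_size), 0) + 1L
  nb <- max(idx)
  counts <- tabulate(idx, nbins = nb)
  data.frame(left_edge = origin + (seq_len(nb) - 1L) * bin_size,
             count = counts)
}

#' Expression-matched correlation control
#'
#' Repeatedly samples non-essential genes so that their mRNA-abundance
#' histogram matches the essential genes' histogram bin-for-bin, and
#' records the Spearman mRNA-protein correlation of each matched sample.
#' If the essential correlation exceeds the bulk of this distribution, the
#' elevated coupling is not attributable to expression level alone.
#'
#' @param pair A `profile_pair`.
#' @param partition Result of [partition_by_essentiality()].
#' @param n_iter Number of matched samples (default 1000).
#' @param bin_width Matching histogram bin width in log2 units (default 1).
#' @param max_boundary_merges Common-support coarsening: an infeasible
#'   *boundary* bin (the extreme tail of the essential distribution, where
#'   the pool may hold fewer genes than needed by chance) is merged into
#'   its inner neighbor, at most this many times per side (default 2).
#'   Central infeasible bins always raise an error.
#' @param seed Optional integer seed.
#' @param keep_samples If `TRUE`, also return the sampled gene ids per
#'   iteration (for auditing the per-bin histogram match).
#' @return List with `rho_e`, `matched` (numeric vector of length
#'   `n_iter`), `quantile` (fraction of matched samples with rho <=
#'   `rho_e`; `NA` when `n_iter` is 0), `bins` (the matched histogram), and
#'   optionally `samples`.
#' @export
expression_matched_rho <- function(pair, partition, n_iter = 1000,
                                   bin_width = 1, max_boundary_merges = 2,
                                   seed = NULL, keep_samples = FALSE) {
  stopifnot(inherits(pair, "profile_pair"))
  if (!is.null(seed)) set.seed(seed)
  ess <- partition$essential
  non <- partition$non_essential
  assert_that(length(ess) >= 3L, "need at least 3 essential genes to match")
  rvals <- stats::setNames(pair$mrna$value, pair$mrna$gene_id)
  bin_of <- function(v) floor(v / bin_width)
  ess_bins <- bin_of(rvals[ess])
  pool_bins <- bin_of(rvals[non])
  count_in <- function(tab, b) if (b %in% names(tab)) tab[[b]] else 0L
  # coarsen infeasible boundary bins inward (extreme-tail Poisson noise),
  # then demand strict per-bin feasibility
  for (side in c("top", "bottom")) {
    for (i in seq_len(max_boundary_merges)) {
      need <- table(ess_bins)
      if (length(need) < 2L) break
      b <- if (side == "top") names(need)[length(need)] else names(need)[1L]
      if (count_in(table(pool_bins), b) >= need[[b]]) break
      inner <- as.numeric(b) + if (side == "top") -1 else 1
      ess_bins[ess_bins == as.numeric(b)] <- inner
    }
  }
  need <- table(ess_bins)
  have <- table(pool_bins)
  for (b in names(need)) {
    assert_that(count_in(have, b) >= need[[b]],
                "infeasible matching: bin [%s, %s) needs %d non-essential genes but the pool has %d",
                format(as.numeric(b) * bin_width),
                format((as.numeric(b) + 1) * bin_width), need[[b]],
                count_in(have, b))
  }
  v_e <- paired_values(pair, ess)
  rho_e <- spearman(v_e$r, v_e$p)$rho
  pool_by_bin <- split(non, pool_bins)
  samples <- if (keep_samples) vector("list", n_iter) else NULL
  matched <- vapply(seq_len(n_iter), function(i) {
    sel <- unlist(lapply(names(need), function(b) {
      pool <- pool_by_bin[[b]]
      pool[sample.int(length(pool), need[[b]])]
    }), use.names = FALSE)
    if (keep_samples) samples[[i]] <<- sel
    v <- paired_values(pair, sel)
    spearman(v$r, v$p)$rho
  }, 0)
  out <- list(rho_e = rho_e, matched = matched,
              quantile = if (n_iter > 0) mean(matched <= rho_e) else NA_real_,
              bins = list(need = need, bin_width = bin_width,
                          bin_of = ess_bins))
  if (keep_samples) out$samples <- samples
  out
}
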
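# Gene-specific RNA-to-protein (RTP) conversion factors: computation over
# a training set of conditions, protein prediction for a target condition,
# leave-one-out cross-species validation, and a randomized (k = h) null
# that preserves biologically plausible ptr ratios.

# Orthogroups single-copy and paired-detected in every one of `conds`;
# returns character vector.
shared_scope <- function(pairs, map, conds = names(pairs)) {
  per_cond <- lapply(conds, function(cond) {
    sc <- single_copy_genes(map, cond)  # gene -> og
    unname(sc[names(sc) %in% pairs[[cond]]$paired_ids])
  })
  Reduce(intersect, per_cond)
}

# For one condition: named vectors of R, P and ptr = P - R indexed by
# orthogroup, over `ogs` (which must all be single-copy + paired there).
og_profile <- function(pair, map, ogs) {
  sc <- single_copy_genes(map, pair$condition_id)
  genes <- stats::setNames(names(sc), unname(sc))[ogs]
  v <- paired_values(pair, unname(genes))
  list(genes = genes,
       r = stats::setNames(as.numeric(v$r), ogs),
       p = stats::setNames(as.numeric(v$p), ogs))
}

#' Compute gene-specific RTP conversion factors
#'
#' For each orthogroup j in scope, the conversion factor is the mean over
#' the N training conditions of the per-condition log2 ptr ratio
#' `P_ij - R_ij`. Orthogroups not single-copy and paired-detected in every
#' training condition are excluded with a report, never imputed.
#'
#' @param pairs Named list of training `profile_pair` objects.
#' @param map An `ortholog_map`.
#' @param gene_scope Optional orthogroup ids to restrict to.
#' @return An `rtp_factor_set`: data frame with columns `orthogroup` and
#'   `factor`, attributes `training` (condition ids), `n_training`, and
#'   `dropped` (requested orthogroups excluded for missing coverage).
#' @export
compute_rtp <- function(pairs, map, gene_scope = NULL) {
  assert_that(length(pairs) >= 1L, "compute_rtp: need >= 1 training condition")
  conds <- names(pairs)
  scope <- shared_scope(pairs, map, conds)
  dropped <- character(0)
  if (!is.null(gene_scope)) {
    dropped <- setdiff(gene_scope, scope)
    scope <- intersect(gene_scope, scope)
  }
  assert_that(length(scope) >= 1L,
              "compute_rtp: no orthogroup is single-copy and paired-detected in all of: %s",
              paste(conds, collapse = ", "))
  ptr_mat <- vapply(conds, function(cond) {
    prof <- og_profile(pairs[[cond]], map, scope)
    prof$p - prof$r
  }, numeric(length(scope)))
  ptr_mat <- matrix(ptr_mat, nrow = length(scope),
                    dimnames = list(scope, conds))
  out <- data.frame(orthogroup = scope, factor = rowMeans(ptr_mat),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "training") <- conds
  attr(out, "n_training") <- length(conds)
  attr(out, "dropped") <- dropped
  class(out) <- c("rtp_factor_set", "data.frame")
  out
}

#' Predict protein levels from mRNA using RTP factors
#'
#' `P_pred = RTP_j + R_ij` on the log2 scale, for orthogroups with a factor
#' whose single-copy gene has detected mRNA in the target condition.
#'
#' @param factors An `rtp_factor_set`.
#' @param target A `profile_pair` for the target condition (which need not
#'   be in the training set).
#' @param map An `ortholog_map`.
#' @return Data frame with columns `orthogroup`, `gene_id`, `r`, `p_pred`;
#'   attribute `skipped` lists factors without a usable target gene.
#' @export
predict_protein <- function(factors, target, map) {
  stopifnot(inherits(factors, "rtp_factor_set"), inherits(target, "profile_pair"))
  sc <- single_copy_genes(map, target$condition_id)  # gene -> og
  og_to_gene <- stats::setNames(names(sc), unname(sc))
  rvals <- stats::setNames(target$mrna$value, target$mrna$gene_id)
  gene <- og_to_gene[factors$orthogroup]
  usable <- !is.na(gene) & gene %in% names(rvals)
  skipped <- factors$orthogroup[!usable]
  out <- data.frame(orthogroup = factors$orthogroup[usable],
                    gene_id = unname(gene[usable]),
                    r = as.numeric(rvals[gene[usable]]),
                    p_pred = factors$factor[usable] + as.numeric(rvals[gene[usable]]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Evaluate an RTP correction on a target condition
#'
#' On the genes with both a prediction and an observed paired protein
#' value, computes the Spearman correlation of observed protein with mRNA
#' (`rho_before`, the uncorrected mRNA-protein coupling) and with the
#' predicted protein (`rho_after`).
#'
#' @param target A `profile_pair`.
#' @param prediction Result of [predict_protein()].
#' @return An `evaluation_result`: list with `condition_id`, `n`,
#'   `rho_before`, `rho_after`, `delta` (`NA` markers when fewer than 3
#'   usable genes).
#' @export
evaluate_correction <- function(target, prediction) {
  stopifnot(inherits(target, "profile_pair"))
  keep <- prediction$gene_id %in% target$paired_ids
  genes <- prediction$gene_id[keep]
  if (length(genes) < 3L) {
    return(structure(list(condition_id = target$condition_id,
                          n = length(genes), rho_before = NA_real_,
                          rho_after = NA_real_, delta = NA_real_),
                     class = "evaluation_result"))
  }
  v <- paired_values(target, genes)
  rho_before <- spearman(v$r, v$p)$rho
  rho_after <- spearman(prediction$p_pred[keep], v$p)$rho
  structure(list(condition_id = target$condition_id, n = length(genes),
                 rho_before = rho_before, rho_after = rho_after,
                 delta = rho_after - rho_before),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s: rho_S = %.3f -> rho_corrected = %.3f (n = %d)\n",
              x$condition_id, x$rho_before, x$rho_after, x$n))
  invisible(x)
}

#' Leave-one-out cross-species validation
#'
#' For each condition in turn, computes left-out conversion factors
#' `LF_j` from the remaining N - 1 conditions, predicts the held-out
#' condition's proteins from its mRNA, and evaluates the correction. The
#' per-condition (rho_before, rho_after) pairs are aggregated with a
#' one-sided exact signed-rank test of improvement.
#'
#' @param pairs Named list of `profile_pair` objects (>= 2 conditions).
#' @param map An `ortholog_map`.
#' @param gene_scope Optional orthogroup restriction; default: orthogroups
#'   single-copy and paired-detected in every condition, so training and
#'   evaluation use one common gene set.
#' @return List with `results` (data frame: condition, n, rho_before,
#'   rho_after, delta), `evaluations` (list of `evaluation_result`),
#'   `factors` (list of `rtp_factor_set` per held-out condition), and
#'   `p_value` (one-sided signed-rank, improvement).
#' @export
leave_one_out <- function(pairs, map, gene_scope = NULL) {
  assert_that(length(pairs) >= 2L, "leave_one_out: need >= 2 conditions")
  conds <- names(pairs)
  scope <- gene_scope %||% shared_scope(pairs, map, conds)
  assert_that(length(scope) >= 1L,
              "leave_one_out: empty orthogroup scope across: %s",
              paste(conds, collapse = ", "))
  evals <- list()
  factor_sets <- list()
  for (cond in conds) {
    lf <- compute_rtp(pairs[setdiff(conds, cond)], map, gene_scope = scope)
    pred <- predict_protein(lf, pairs[[cond]], map)
    evals[[cond]] <- evaluate_correction(pairs[[cond]], pred)
    factor_sets[[cond]] <- lf
  }
  res <- do.call(rbind, lapply(evals, function(e) {
    data.frame(condition = e$condition_id, n = e$n,
               rho_before = e$rho_before, rho_after = e$rho_after,
               delta = e$delta, stringsAsFactors = FALSE)
  }))
  row.names(res) <- NULL
  ok <- is.finite(res$rho_before) & is.finite(res$rho_after)
  test <- if (any(ok)) {
    signed_rank_test(res$rho_before[ok], res$rho_after[ok], "greater")
  } else {
    list(p_value = NA_real_, degenerate = TRUE)
  }
  list(results = res, evaluations = evals, factors = factor_sets,
       p_value = test$p_value, test = test, scope = scope)
}

#' Randomized (k = h) null for RTP factors
#'
#' Builds null conversion factors by replacing, independently for every
#' orthogroup j, training condition i and draw, the orthologous gene's ptr
#' ratio with the ptr ratio of a uniformly sampled NON-orthologous
#' paired-detected gene of that condition. Because the sampled protein and
#' mRNA values come from the same gene (k = h), each null factor is still a
#' biologically plausible ptr ratio; what is destroyed is the gene-specific
#' correspondence. Each draw is evaluated on the target exactly like a real
#' correction.
#'
#' @param pairs Named list of training `profile_pair` objects.
#' @param target A `profile_pair` to evaluate on.
#' @param map An `ortholog_map`.
#' @param gene_scope Optional orthogroup restriction (default: shared
#'   training scope).
#' @param n_draws Number of null draws (default 200).
#' @param seed Optional integer seed; fixed seed gives an identical null
#'   distribution on repeat.
#' @return Data frame (one row per draw) with `draw`, `n`, `rho_before`,
#'   `rho_after`, `delta`.
#' @export
randomized_rtp <- function(pairs, target, map, gene_scope = NULL,
                           n_draws = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- names(pairs)
  scope <- gene_scope %||% shared_scope(pairs, map, conds)
  assert_that(length(scope) >= 1L, "randomized_rtp: empty orthogroup scope")
  # per training condition: ptr ratios of non-orthologous paired genes
  null_pools <- lapply(conds, function(cond) {
    pair <- pairs[[cond]]
    og_genes <- unlist(lapply(map$groups, function(g) g[[cond]]), use.names = FALSE)
    genes <- setdiff(pair$paired_ids, og_genes)
    assert_that(length(genes) >= 1L,
                "randomized_rtp: condition '%s' has no non-orthologous paired genes",
                cond)
    v <- paired_values(pair, genes)
    as.numeric(v$p - v$r)
  })
  names(null_pools) <- conds
  nj <- length(scope)
  rows <- lapply(seq_len(n_draws), function(dr) {
    ptr_draws <- vapply(conds, function(cond) {
      pool <- null_pools[[cond]]
      pool[sample.int(length(pool), nj, replace = TRUE)]
    }, numeric(nj))
    fac <- rowMeans(matrix(ptr_draws, nrow = nj))
    fs <- data.frame(orthogroup = scope, factor = fac, stringsAsFactors = FALSE)
    attr(fs, "training") <- conds
    class(fs) <- c("rtp_factor_set", "data.frame")
    pred <- predict_protein(fs, target, map)
    ev <- evaluate_correction(target, pred)
    data.frame(draw = dr, n = ev$n, rho_before = ev$rho_before,
               rho_after = ev$rho_after, delta = ev$delta)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
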
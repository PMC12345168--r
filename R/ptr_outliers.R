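# Genome-wide log2 protein ~ mRNA regression, standardized residuals,
# high/low ptr outlier classification, and cross-condition ranking of
# conserved extreme orthologs.

#' Fit the genome-wide protein ~ mRNA regression
#'
#' Ordinary least squares of the paired log2 protein values on the paired
#' log2 mRNA values (closed form). The residual scale `s` uses the usual
#' n - 2 degrees of freedom.
#'
#' @param pair A `profile_pair`.
#' @param genes Gene set to fit on (default: the paired set).
#' @return A `ptr_regression`: list with `condition_id`, `slope`,
#'   `intercept`, `s`, `n`.
#' @export
fit_ptr_regression <- function(pair, genes = pair$paired_ids) {
  stopifnot(inherits(pair, "profile_pair"))
  assert_that(length(genes) >= 3L,
              "fit_ptr_regression: need >= 3 paired genes, got %d", length(genes))
  v <- paired_values(pair, genes)
  fit <- fit_r_squared(v$r, v$p)
  n <- length(genes)
  sse <- sum((v$p - fit$intercept - fit$slope * v$r)^2)
  structure(list(condition_id = pair$condition_id,
                 slope = fit$slope, intercept = fit$intercept,
                 s = sqrt(sse / (n - 2)), n = n, genes = genes),
            class = "ptr_regression")
}

#' @export
print.ptr_regression <- function(x, ...) {
  cat(sprintf("<ptr_regression> %s: P = %.3f + %.3f R, s = %.3f (n = %d)\n",
              x$condition_id, x$intercept, x$slope, x$s, x$n))
  invisible(x)
}

#' Standardized residuals and outlier classes
#'
#' For each gene, `z = (P - (intercept + slope * R)) / s`. Genes with
#' `z >= 2` are classed `high` (more protein than the genome-wide trend
#' predicts), `z <= -2` are `low`, all others `none`. The per-gene ptr
#' ratio `P - R` is recorded alongside.
#'
#' @param model A `ptr_regression` fitted on this pair.
#' @param pair The same `profile_pair`.
#' @param map Optional `ortholog_map`; when given, each gene's single-copy
#'   orthogroup (or `NA`) is annotated.
#' @param threshold Outlier threshold on `|z|` (default 2).
#' @return Data frame (class `outlier_records`) with columns `gene_id`,
#'   `orthogroup`, `ptr`, `z`, `class`, plus attribute `condition_id`.
#' @export
standardized_residuals <- function(model, pair, map = NULL, threshold = 2) {
  stopifnot(inherits(model, "ptr_regression"), inherits(pair, "profile_pair"))
  assert_that(identical(model$condition_id, pair$condition_id),
              "model fitted on '%s' but profiles are '%s'",
              model$condition_id, pair$condition_id)
  genes <- model$genes
  v <- paired_values(pair, genes)
  resid <- v$p - model$intercept - model$slope * v$r
  z <- if (model$s > 0) resid / model$s else rep(0, length(resid))
  cls <- ifelse(z >= threshold, "high", ifelse(z <= -threshold, "low", "none"))
  og <- rep(NA_character_, length(genes))
  if (!is.null(map)) {
    sc <- single_copy_genes(map, pair$condition_id)
    hit <- match(genes, names(sc))
    og[!is.na(hit)] <- unname(sc[hit[!is.na(hit)]])
  }
  out <- data.frame(gene_id = genes, orthogroup = og,
                    ptr = as.numeric(v$p - v$r), z = as.numeric(z),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "condition_id") <- pair$condition_id
  class(out) <- c("outlier_records", "data.frame")
  out
}

#' Tabulate outlier classes per condition
#'
#' @param records Named list of `outlier_records` (one per condition) or a
#'   single `outlier_records`.
#' @return Data frame with columns `condition`, `low`, `high`.
#' @export
count_outlier_classes <- function(records) {
  if (inherits(records, "outlier_records")) {
    records <- stats::setNames(list(records), attr(records, "condition_id"))
  }
  rows <- lapply(names(records), function(cond) {
    r <- records[[cond]]
    data.frame(condition = cond,
               low = sum(r$class == "low"),
               high = sum(r$class == "high"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank conserved extreme-ptr orthologs across conditions
#'
#' Restricts to orthogroups that are single-copy and have a standardized
#' residual in every requested condition, averages the per-condition z
#' values after clipping at `+/- clip` (so a single extreme condition
#' cannot dominate the mean), and ranks orthogroups by that clipped mean.
#'
#' @param records Named list of `outlier_records` keyed by condition id.
#' @param map An `ortholog_map`.
#' @param conditions Conditions to average over (default: all in
#'   `records`). In a study with an archaeal outgroup this is typically the
#'   bacterial subset.
#' @param clip Absolute clip applied to z before averaging (default 2).
#' @param k Size of the top/bottom lists (default 15).
#' @return List with matrices `z` and `ptr` (orthogroup x condition),
#'   `mean_z` (named, sorted decreasing; ties broken by orthogroup id),
#'   `ranking` (data frame orthogroup/mean_z/rank), `top`, `bottom`
#'   (orthogroup ids), and `excluded` (orthogroups lacking a z in some
#'   condition, with the reason).
#' @export
conserved_ranking <- function(records, map, conditions = names(records),
                              clip = 2, k = 15) {
  assert_that(all(conditions %in% names(records)),
              "missing outlier records for condition(s): %s",
              paste(setdiff(conditions, names(records)), collapse = ", "))
  # orthogroup -> z and ptr per condition (single-copy only)
  per_cond <- lapply(conditions, function(cond) {
    r <- records[[cond]]
    keep <- !is.na(r$orthogroup) & !duplicated(r$orthogroup)
    list(z = stats::setNames(r$z[keep], r$orthogroup[keep]),
         ptr = stats::setNames(r$ptr[keep], r$orthogroup[keep]))
  })
  names(per_cond) <- conditions
  covered <- names(map$groups)[vapply(names(map$groups), function(og) {
    all(vapply(conditions, function(cond) og_single_copy(map, og, cond) &&
                 length(map$groups[[og]][[cond]]) == 1L, TRUE))
  }, TRUE)]
  has_z <- vapply(covered, function(og) {
    all(vapply(conditions, function(cond) og %in% names(per_cond[[cond]]$z), TRUE))
  }, TRUE)
  excluded <- covered[!has_z]
  ogs <- covered[has_z]
  assert_that(length(ogs) >= 1L,
              "no orthogroup has standardized residuals in all of: %s",
              paste(conditions, collapse = ", "))
  zmat <- sapply(conditions, function(cond) per_cond[[cond]]$z[ogs])
  pmat <- sapply(conditions, function(cond) per_cond[[cond]]$ptr[ogs])
  zmat <- matrix(zmat, nrow = length(ogs), dimnames = list(ogs, conditions))
  pmat <- matrix(pmat, nrow = length(ogs), dimnames = list(ogs, conditions))
  mean_z <- rowMeans(clamp(zmat, -clip, clip))
  ord <- order(-mean_z, ogs)
  mean_z <- mean_z[ord]
  kk <- min(k, length(ogs))
  ranking <- data.frame(orthogroup = names(mean_z), mean_z = as.numeric(mean_z),
                        rank = seq_along(mean_z), stringsAsFactors = FALSE)
  list(z = zmat[ord, , drop = FALSE], ptr = pmat[ord, , drop = FALSE],
       mean_z = mean_z, ranking = ranking,
       top = ranking$orthogroup[seq_len(kk)],
       bottom = rev(ranking$orthogroup[seq(nrow(ranking) - kk + 1L, nrow(ranking))]),
       excluded = excluded, clip = clip, conditions = conditions)
}
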
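# Readers and writers for every on-disk format the pipeline touches:
# per-condition abundance TSVs (gene_id + one column per replicate),
# OrthoFinder-style Orthogroups.tsv, and plain-text gene lists.

#' Construct an abundance table
#'
#' An abundance table holds raw (or normalized) per-replicate gene
#' abundances for a single condition and a single modality (mRNA counts or
#' protein reporter-ion intensities).
#'
#' @param condition_id Condition label (e.g. a species/strain/medium code).
#' @param modality Either `"mRNA"` or `"protein"`.
#' @param gene_ids Character vector of unique gene identifiers.
#' @param values Numeric matrix, genes x replicates, non-negative and finite.
#' @param replicate_ids Optional replicate labels (default `rep1`, ...).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(condition_id, modality, gene_ids, values,
                            replicate_ids = NULL) {
  modality <- match.arg(modality, c("mRNA", "protein"))
  values <- as.matrix(values)
  if (is.null(replicate_ids)) {
    replicate_ids <- colnames(values) %||% paste0("rep", seq_len(ncol(values)))
  }
  assert_that(ncol(values) >= 2L,
              "abundance table '%s': need >= 2 replicate columns, got %d",
              condition_id, ncol(values))
  assert_that(length(gene_ids) == nrow(values),
              "abundance table '%s': %d gene ids but %d rows",
              condition_id, length(gene_ids), nrow(values))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  assert_that(length(dup) == 0L,
              "abundance table '%s': duplicate gene id(s): %s",
              condition_id, paste(utils::head(dup, 5), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_fmt("abundance table '%s': negative or non-finite value at gene '%s', replicate '%s'",
             condition_id, gene_ids[bad[1, 1]], replicate_ids[bad[1, 2]])
  }
  dimnames(values) <- list(gene_ids, replicate_ids)
  structure(list(condition_id = condition_id, modality = modality,
                 gene_ids = gene_ids, values = values,
                 replicate_ids = replicate_ids),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %s [%s]: %d genes x %d replicates\n",
              x$condition_id, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an abundance table from TSV
#'
#' Expects a header row naming the replicates, a first column of gene IDs,
#' and one numeric column per replicate.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams abundance_table
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, condition_id, modality) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3L,
              "abundance table '%s': fewer than 2 replicate columns in %s",
              condition_id, path)
  gene_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  abundance_table(condition_id, modality, gene_ids, vals,
                  replicate_ids = colnames(df)[-1])
}

#' Write an abundance table to TSV
#'
#' Values are written with 17 significant digits so that a
#' write/read round trip is the identity on double-precision values.
#'
#' @param table An `abundance_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  txt <- apply(table$values, 2, function(col) formatC(col, digits = 17, format = "g"))
  df <- data.frame(gene_id = table$gene_ids, txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", table$replicate_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an ortholog map
#'
#' @param groups Named list: orthogroup id -> named list mapping condition id
#'   to a character vector of gene ids (conditions with no genes omitted).
#' @param condition_ids Ordered condition labels.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(groups, condition_ids) {
  for (cond in condition_ids) {
    genes <- unlist(lapply(groups, function(g) g[[cond]]), use.names = FALSE)
    dup <- unique(genes[duplicated(genes)])
    assert_that(length(dup) == 0L,
                "gene '%s' assigned to more than one orthogroup in condition '%s'",
                dup[1], cond)
  }
  structure(list(groups = groups, condition_ids = condition_ids),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d orthogroups x %d conditions\n",
              length(x$groups), length(x$condition_ids)))
  invisible(x)
}

#' Orthogroup coverage
#'
#' @param map An `ortholog_map`.
#' @param orthogroup Orthogroup id.
#' @return Character vector of condition ids in which the orthogroup has at
#'   least one gene.
#' @export
og_coverage <- function(map, orthogroup) {
  g <- map$groups[[orthogroup]]
  assert_that(!is.null(g), "unknown orthogroup '%s'", orthogroup)
  names(g)[vapply(g, length, 1L) > 0L]
}

#' Single-copy status of an orthogroup in a condition
#'
#' @inheritParams og_coverage
#' @param condition_id Condition label.
#' @return `TRUE` iff the orthogroup has exactly one gene in the condition.
#' @export
og_single_copy <- function(map, orthogroup, condition_id) {
  g <- map$groups[[orthogroup]]
  assert_that(!is.null(g), "unknown orthogroup '%s'", orthogroup)
  length(g[[condition_id]]) == 1L
}

# Named vector gene_id -> orthogroup id, restricted to single-copy entries
# for one condition. Internal workhorse for pairwise/ranking/transfer code.
single_copy_genes <- function(map, condition_id) {
  keep <- vapply(map$groups, function(g) length(g[[condition_id]]) == 1L, TRUE)
  genes <- vapply(map$groups[keep], function(g) g[[condition_id]], "")
  stats::setNames(names(genes), genes)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' Column 1 is the orthogroup id; the remaining columns (one per condition)
#' hold comma-separated gene lists; an empty cell means the orthogroup is
#' absent from that condition. Both the OrthoFinder v2 `", "` separator and a
#' bare `","` are accepted.
#'
#' @param path Path to the TSV.
#' @param condition_ids Expected condition columns (order-insensitive).
#' @return An `ortholog_map` with conditions ordered as `condition_ids`.
#' @export
read_orthogroups <- function(path, condition_ids) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  header <- colnames(df)[-1]
  unknown <- setdiff(header, condition_ids)
  assert_that(length(unknown) == 0L,
              "orthogroups file has unknown condition column(s): %s",
              paste(unknown, collapse = ", "))
  missing <- setdiff(condition_ids, header)
  assert_that(length(missing) == 0L,
              "orthogroups file is missing condition column(s): %s",
              paste(missing, collapse = ", "))
  ogs <- as.character(df[[1]])
  groups <- lapply(seq_along(ogs), function(i) {
    row <- lapply(condition_ids, function(cond) {
      cell <- df[i, cond]
      if (is.na(cell) || !nzchar(trimws(cell))) return(NULL)
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      genes[nzchar(genes)]
    })
    names(row) <- condition_ids
    row[!vapply(row, is.null, TRUE)]
  })
  names(groups) <- ogs
  ortholog_map(groups, condition_ids)
}

#' Write an ortholog map as Orthogroups.tsv
#'
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orthogroups <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  cols <- lapply(map$condition_ids, function(cond) {
    vapply(map$groups, function(g) paste(g[[cond]], collapse = ", "), "")
  })
  df <- data.frame(Orthogroup = names(map$groups), cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("Orthogroup", map$condition_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line)
#'
#' Blank lines are ignored and duplicates are dropped with a message.
#' An empty file yields an empty set with a warning.
#'
#' @param path Path to the list.
#' @return Character vector of unique gene ids, with attribute
#'   `n_duplicates` recording how many duplicate lines were dropped.
#' @export
read_gene_list <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  ndup <- sum(duplicated(ids))
  if (ndup > 0L) message(sprintf("read_gene_list: dropped %d duplicate id(s)", ndup))
  out <- unique(ids)
  if (length(out) == 0L) warning("gene list is empty: ", path)
  attr(out, "n_duplicates") <- ndup
  out
}

#' Write a gene list (one id per line)
#'
#' @param ids Character vector of gene ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
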
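# Shared fixture builders (everything generated in code; no data files).

# Small, fast generator configuration for unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_conditions = 4, genes_per_condition = 250, n_orthogroups = 60,
         n_shared_all = 15, n_shared_bacterial = 10),
    list(...))
  do.call(synthetic_config, args)
}

# Noise-free configuration: raw log2(protein) - log2(mRNA) equals c_j
noise_free_config <- function(...) {
  args <- utils::modifyList(
    list(replicate_noise_sd = 0, species_ptr_sd = 0,
         measurement_noise_sd = 0, outlier_fraction = 0,
         protein_dropout_midpoint = -Inf, mrna_library_depth = NA,
         normalize_latents = FALSE),
    list(...))
  do.call(synthetic_config, args)
}

# Profile pair straight from log2 value vectors
make_pair <- function(r, p, condition = "C1",
                      genes = sprintf("g%03d", seq_along(r))) {
  profile_pair(condition,
               data.frame(gene_id = genes, value = r, stringsAsFactors = FALSE),
               data.frame(gene_id = genes, value = p, stringsAsFactors = FALSE))
}

# Abundance table from a matrix (genes in rows)
make_table <- function(values, condition = "C1", modality = "mRNA",
                       genes = sprintf("g%03d", seq_len(nrow(as.matrix(values))))) {
  abundance_table(condition, modality, genes, as.matrix(values))
}
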
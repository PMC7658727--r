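# Shared fixtures: built in code at test time, nothing stored on disk.

# small 3-subtype cohort for fast end-to-end tests
small_cohort <- function(seed = 101L, effect_size = 2, n_samples = 20L) {
  generate_cohort(synthetic_config(
    n_subtypes = 3L, genes_per_signature = 6L, n_background_genes = 20L,
    n_samples_per_subtype = n_samples, effect_size = effect_size,
    noise_sd = 1, seed = seed))
}

small_model <- function(cohort, seed = 5L, n_members = 4L) {
  fit_subtype_model(cohort$expression, cohort$labels, cohort$signatures,
                    training_config(n_members = n_members, nrounds = 15L,
                                    seed = seed))
}

# independent brute-force oracle for the signature-pair score: an explicit
# double loop, no vectorization shared with the implementation
brute_force_sig_pair <- function(values, sig_m, sig_n) {
  wins <- 0L; k <- 0L
  for (i in sig_m) for (j in sig_n) {
    if (i == j) next
    vi <- values[[i]]; vj <- values[[j]]
    if (is.na(vi) || is.na(vj)) next
    k <- k + 1L
    if (vi > vj) wins <- wins + 1L
  }
  if (k == 0L) return(NA_real_)
  wins / k
}

write_expr_file <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

prob_cols <- function(pred) as.matrix(pred[, grep("^prob_", names(pred)), drop = FALSE])
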
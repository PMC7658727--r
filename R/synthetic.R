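# Synthetic subtype-structured cohorts. A deliberately minimal log-normal
# generative model: each subtype up-shifts the log-expression of its own
# signature's genes, which is exactly the kind of structure the rank features
# can detect. Not a model of real tumor expression (no purity, batch, or
# count-level noise).

#' Configuration for the synthetic cohort generator
#'
#' @param n_subtypes Number of latent subtypes (labels `C1..CK`).
#' @param n_signatures Number of signatures; must equal `n_subtypes` so the
#'   signatures map 1:1 to subtypes.
#' @param genes_per_signature Genes drawn for each signature.
#' @param n_background_genes Unshifted background genes.
#' @param n_samples_per_subtype Samples per subtype.
#' @param effect_size Mean log-expression shift added to a subtype's own
#'   signature genes in samples of that subtype (log scale, so 2 means
#'   e^2-fold at the median).
#' @param noise_sd Standard deviation of the per-value Gaussian log-noise.
#' @param overlap_genes Number of genes each signature shares with the next
#'   (cyclically); default 0 gives disjoint signatures.
#' @param seed Integer seed; the whole cohort is reproducible from the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subtypes = 6L, n_signatures = n_subtypes,
                             genes_per_signature = 20L,
                             n_background_genes = 200L,
                             n_samples_per_subtype = 100L,
                             effect_size = 2, noise_sd = 1,
                             overlap_genes = 0L, seed = 42L) {
  cfg <- list(n_subtypes = as.integer(n_subtypes),
              n_signatures = as.integer(n_signatures),
              genes_per_signature = as.integer(genes_per_signature),
              n_background_genes = as.integer(n_background_genes),
              n_samples_per_subtype = as.integer(n_samples_per_subtype),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              overlap_genes = as.integer(overlap_genes),
              seed = as.integer(seed))
  with(cfg, {
    if (n_subtypes < 1L || n_signatures < 1L || genes_per_signature < 1L ||
        n_background_genes < 1L || n_samples_per_subtype < 1L)
      stop("all counts must be >= 1", call. = FALSE)
    if (n_signatures != n_subtypes)
      stop("signatures map 1:1 to subtypes; n_signatures must equal n_subtypes",
           call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
    if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
    if (overlap_genes >= genes_per_signature)
      stop("overlap_genes must be < genes_per_signature", call. = FALSE)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a subtype-structured synthetic cohort
#'
#' Gene `g` in signature `k` has log-expression
#' `baseline_g + effect_size` in samples of subtype `k` and `baseline_g`
#' elsewhere; Gaussian noise with `noise_sd` is added and the result is
#' exponentiated to a positive expression scale. Per-gene baselines are drawn
#' `N(4, 1)` so genes span a realistic dynamic range.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `expression` (an `expr_matrix`), `labels` (a
#'   `data.frame` with `sample_id`, `subtype`), and `signatures` (a
#'   [signature_collection()]).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  K <- cfg$n_subtypes
  sig_genes <- lapply(seq_len(K), function(k)
    sprintf("S%dG%02d", k, seq_len(cfg$genes_per_signature)))
  sigs <- sig_genes
  if (cfg$overlap_genes > 0L)
    for (k in seq_len(K))
      sigs[[k]] <- c(sig_genes[[k]],
                     sig_genes[[k %% K + 1L]][seq_len(cfg$overlap_genes)])
  names(sigs) <- sprintf("sig%d", seq_len(K))
  genes <- c(unlist(sig_genes, use.names = FALSE),
             sprintf("BG%04d", seq_len(cfg$n_background_genes)))
  n <- K * cfg$n_samples_per_subtype
  samples <- sprintf("SAMP%04d", seq_len(n))
  subtype <- rep(sprintf("C%d", seq_len(K)), each = cfg$n_samples_per_subtype)

  baseline <- stats::rnorm(length(genes), mean = 4, sd = 1)
  logx <- matrix(baseline, length(genes), n) +
    matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd), length(genes), n)
  for (k in seq_len(K)) {
    rows <- match(sig_genes[[k]], genes)
    cols <- which(subtype == sprintf("C%d", k))
    logx[rows, cols] <- logx[rows, cols] + cfg$effect_size
  }
  vals <- exp(logx)
  dimnames(vals) <- list(genes, samples)
  list(expression = expression_matrix(vals, "hgnc_symbol"),
       labels = data.frame(sample_id = samples, subtype = subtype,
                           stringsAsFactors = FALSE),
       signatures = signature_collection(sigs, "hgnc_symbol"))
}

#' Apply a random strictly increasing per-sample transform
#'
#' Emulates running the same samples through different quantification and
#' normalization pipelines: each sample is distorted by an independently
#' drawn strictly increasing function, which changes every value but no
#' within-sample ordering.
#'
#' @param m An `expr_matrix`.
#' @param family `"affine"` (`a*x + b`, `a > 0`), `"log1p"`
#'   (`log1p(c*x)`, `c > 0`), `"power"` (`x^p`, `p > 0`), or `"rank"`
#'   (within-sample average ranks). `log1p` and `power` require positive
#'   input.
#' @param seed Integer seed for the per-sample parameter draws.
#' @return An `expr_matrix` with the same dimnames.
#' @export
monotone_distort <- function(m, family = c("affine", "log1p", "power", "rank"),
                             seed = 1L) {
  stopifnot(inherits(m, "expr_matrix"))
  family <- match.arg(family)
  vals <- unclass(m)
  if (family %in% c("log1p", "power") && any(vals <= 0, na.rm = TRUE))
    stop("the ", family, " family requires strictly positive expression values",
         call. = FALSE)
  set.seed(seed)
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    vals[, j] <- switch(family,
      affine = stats::runif(1, 0.5, 3) * x + stats::runif(1, 0, 5),
      log1p  = log1p(stats::runif(1, 0.5, 2) * x),
      power  = x ^ stats::runif(1, 0.3, 3),
      rank   = { r <- x; r[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average"); r })
  }
  attr(vals, "namespace") <- NULL
  expression_matrix(vals, attr(m, "namespace"))
}

#' Write a cohort to disk as plain-text fixtures
#'
#' Writes the three files the CLI workflow consumes: `expression.tsv` in the
#' layout [read_expression()] reads, `labels.csv`, and `signatures.gmt`.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.csv"),
             signatures = file.path(dir, "signatures.gmt"))
  df <- data.frame(gene_id = rownames(cohort$expression),
                   unclass(cohort$expression), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$labels, paths[["labels"]], row.names = FALSE,
                   quote = FALSE)
  write_signatures_gmt(cohort$signatures, paths[["signatures"]])
  invisible(paths)
}
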
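# Rank-based single-sample features: quartile bins, binary gene-pair order
# indicators, signature-pair scores. Every feature depends only on the
# ordering of values within one sample, so any strictly increasing per-sample
# transform (library-size scaling, log, rank, power) leaves it unchanged.

#' Define the feature layout for a signature collection
#'
#' Fixes, once, the set and order of features the classifier consumes:
#' one quartile bin per panel gene, one order bit per gene pair in
#' `pair_list`, one signature-pair score per ordered signature pair
#' (including `m == n`), and one score per signature. The order is total and
#' stable, so feature matrices from different runs align column-for-column.
#'
#' @param signatures A [signature_collection()].
#' @param pair_mode How gene pairs for the binary order bits are chosen:
#'   `"auto"` uses all unordered panel pairs when the panel has at most
#'   `panel_pair_limit` genes and otherwise falls back to the pairs induced
#'   within each signature; `"all_panel"` and `"within_signature"` force one
#'   or the other.
#' @param panel_pair_limit Panel size above which `"auto"` switches from all
#'   panel pairs to within-signature pairs (default 100).
#' @return An object of class `feature_spec` with elements `signatures`,
#'   `panel`, `pair_list` (2-column character matrix; the bit is
#'   `gene[,1] > gene[,2]`), and `feature_order`.
#' @export
feature_spec <- function(signatures,
                         pair_mode = c("auto", "all_panel", "within_signature"),
                         panel_pair_limit = 100L) {
  stopifnot(inherits(signatures, "signature_collection"))
  pair_mode <- match.arg(pair_mode)
  pg <- panel(signatures)
  mode <- if (pair_mode == "auto") {
    if (length(pg) <= panel_pair_limit) "all_panel" else "within_signature"
  } else pair_mode
  pair_list <- if (mode == "all_panel") {
    idx <- utils::combn(length(pg), 2L)
    cbind(pg[idx[1L, ]], pg[idx[2L, ]])
  } else {
    pieces <- lapply(signatures, function(g) {
      g <- intersect(pg, g)       # panel order within the signature
      if (length(g) < 2L) return(NULL)
      idx <- utils::combn(length(g), 2L)
      cbind(g[idx[1L, ]], g[idx[2L, ]])
    })
    pl <- do.call(rbind, pieces)
    pl[!duplicated(paste(pl[, 1L], pl[, 2L], sep = "\r")), , drop = FALSE]
  }
  snm <- names(signatures)
  sig_pairs <- expand.grid(n = snm, m = snm, stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)[, c("m", "n")]
  feature_order <- c(
    paste0("q_", pg),
    paste0("gp_", pair_list[, 1L], "..", pair_list[, 2L]),
    paste0("sp_", sig_pairs$m, "..", sig_pairs$n),
    paste0("ss_", snm)
  )
  structure(list(signatures = signatures, panel = pg, pair_list = pair_list,
                 sig_pairs = sig_pairs, feature_order = feature_order),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> panel %d genes, %d gene pairs, %d signatures, %d features\n",
              length(x$panel), nrow(x$pair_list), length(x$signatures),
              length(x$feature_order)))
  invisible(x)
}

# min-rank percentile binning; tied genes share the bin of the lowest rank
# in their tie group, so an all-tied sample sits entirely in bin 1
.quartile_bins <- function(x) {
  b <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 4L)
    stop("quartile binning needs at least 4 non-missing genes, got ", n,
         call. = FALSE)
  pct <- rank(x[ok], ties.method = "min") / n
  b[ok] <- 1 + (pct > 0.25) + (pct > 0.5) + (pct > 0.75)
  b
}

#' Quartile-bin features for one sample
#'
#' Each non-missing panel gene is assigned an ordinal bin 1-4 from its
#' within-sample rank percentile at thresholds 0.25/0.5/0.75; a percentile
#' exactly on a threshold goes to the lower bin, and tied genes take the bin
#' of the lowest rank in their tie group. Missing genes get `NA`.
#'
#' @param values Named numeric vector of one sample's expression over the
#'   panel; `NA` allowed.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of bins in panel order.
#' @export
quartile_features <- function(values, spec) {
  x <- values[spec$panel]
  b <- .quartile_bins(unname(x))
  names(b) <- spec$panel
  b
}

#' Binary gene-pair order features for one sample
#'
#' For each pair `(i, j)` in `spec$pair_list` the bit is 1 when
#' `g_i > g_j` strictly, 0 otherwise (ties give 0), and `NA` when either
#' value is missing — the Top Scoring Pairs encoding.
#'
#' @inheritParams quartile_features
#' @return Named numeric vector of 0/1/`NA` bits, one per pair.
#' @export
gene_pair_features <- function(values, spec) {
  bits <- as.numeric(values[spec$pair_list[, 1L]] > values[spec$pair_list[, 2L]])
  names(bits) <- paste0("gp_", spec$pair_list[, 1L], "..", spec$pair_list[, 2L])
  bits
}

#' Signature-pair score s_mn
#'
#' `s_mn = sum_ij (g_im > g_jn) / k`: the fraction, over all ordered cross
#' pairs of a gene `i` from signature `m` against a gene `j` from signature
#' `n`, of pairs where the `m` gene strictly exceeds the `n` gene. Pairs where
#' `i` and `j` are the same gene (shared between the two signatures) are
#' excluded, as are pairs involving a missing value; `k` counts the pairs
#' actually compared, so the score lies in `[0, 1]`.
#'
#' @param values Named numeric vector of one sample's expression.
#' @param sig_m,sig_n Character vectors of gene identifiers.
#' @return A single number in `[0, 1]`.
#' @export
signature_pair_score <- function(values, sig_m, sig_n) {
  gm <- intersect(sig_m, names(values)[!is.na(values)])
  gn <- intersect(sig_n, names(values)[!is.na(values)])
  cmp <- outer(values[gm], values[gn], `>`)
  same <- outer(gm, gn, `==`)
  k <- sum(!same)
  if (k == 0L)
    stop("no comparable gene pairs between the two signatures (k = 0)",
         call. = FALSE)
  sum(cmp & !same) / k
}

#' Signature score for one sample
#'
#' Mean within-sample rank percentile (average-rank ties, percentile =
#' rank / number of non-missing genes) of the signature's genes; a reporting
#' summary of how highly a signature is expressed, in `(0, 1]`.
#'
#' @inheritParams signature_pair_score
#' @param sig Character vector of gene identifiers.
#' @return A single number in `(0, 1]`.
#' @export
signature_score <- function(values, sig) {
  ok <- !is.na(values)
  pct <- rank(values[ok], ties.method = "average") / sum(ok)
  hit <- intersect(sig, names(values)[ok])
  if (length(hit) == 0L)
    stop("signature has no non-missing genes in this sample", call. = FALSE)
  mean(pct[hit])
}

#' Build the full feature vector for one sample
#'
#' Assembles quartile bins, gene-pair bits, all ordered signature-pair scores,
#' and signature scores in `spec$feature_order`. Computed from this sample
#' alone — no other sample enters.
#'
#' @inheritParams quartile_features
#' @return Named numeric vector of length `length(spec$feature_order)`.
#' @export
build_feature_vector <- function(values, spec) {
  m <- matrix(values[spec$panel], ncol = 1L,
              dimnames = list(spec$panel, "sample"))
  build_feature_matrix(expression_matrix(m, attr(spec$signatures, "namespace")),
                       spec)[1L, ]
}

#' Build the feature matrix for a cohort
#'
#' Vectorized, per-sample-independent computation of [build_feature_vector()]
#' for every column of an expression matrix. The input is first restricted to
#' the spec's panel (see [subset_to_panel()]).
#'
#' @param m An `expr_matrix`.
#' @param spec A [feature_spec()].
#' @param min_coverage Passed to [subset_to_panel()].
#' @return Numeric samples x features matrix with columns
#'   `spec$feature_order`.
#' @export
build_feature_matrix <- function(m, spec, min_coverage = 0.6) {
  stopifnot(inherits(m, "expr_matrix"), inherits(spec, "feature_spec"))
  X <- unclass(subset_to_panel(m, spec$signatures, min_coverage = min_coverage))
  ns <- ncol(X)

  qb <- apply(X, 2L, .quartile_bins)             # panel x samples

  i1 <- match(spec$pair_list[, 1L], spec$panel)
  i2 <- match(spec$pair_list[, 2L], spec$panel)
  gp <- (X[i1, , drop = FALSE] > X[i2, , drop = FALSE]) + 0  # NA propagates

  # ordered signature-pair scores via one grouped comparison table
  sp <- matrix(NA_real_, nrow(spec$sig_pairs), ns)
  cross <- lapply(seq_len(nrow(spec$sig_pairs)), function(p) {
    gm <- spec$signatures[[spec$sig_pairs$m[p]]]
    gn <- spec$signatures[[spec$sig_pairs$n[p]]]
    g <- expand.grid(i = match(gm, spec$panel), j = match(gn, spec$panel),
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[g$i != g$j, , drop = FALSE]           # shared genes excluded
    cbind(p = p, i = g$i, j = g$j)
  })
  cross <- do.call(rbind, cross)
  ind <- X[cross[, "i"], , drop = FALSE] > X[cross[, "j"], , drop = FALSE]
  wins <- rowsum(ifelse(is.na(ind), 0, ind + 0), cross[, "p"])
  valid <- rowsum((!is.na(ind)) + 0, cross[, "p"])
  if (any(valid == 0))
    stop("signature pair with no comparable genes (k = 0) in sample(s): ",
         paste(colnames(X)[colSums(valid == 0) > 0], collapse = ", "),
         call. = FALSE)
  sp[as.integer(rownames(wins)), ] <- wins / valid

  ss <- apply(X, 2L, function(x) {
    ok <- !is.na(x)
    pct <- rank(x[ok], ties.method = "average") / sum(ok)
    vapply(spec$signatures, function(g) {
      hit <- intersect(g, names(x)[ok])
      if (length(hit) == 0L)
        stop("signature has no non-missing genes in a sample", call. = FALSE)
      mean(pct[hit])
    }, numeric(1))
  })
  ss <- matrix(ss, nrow = length(spec$signatures))  # robust when 1 signature

  out <- t(rbind(qb, gp, sp, ss))
  dimnames(out) <- list(colnames(X), spec$feature_order)
  out
}
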
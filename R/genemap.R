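# Expression-matrix and gene-set I/O with identifier-namespace handling.

.NAMESPACES <- c("hgnc_symbol", "entrez", "ensembl")

#' Construct an expression matrix
#'
#' Wraps a genes x samples numeric matrix together with the identifier
#' namespace of its row names. Row names are gene identifiers (one namespace
#' per matrix), column names are sample identifiers; both must be unique.
#' Values may be `NA` (explicitly missing) but not infinite.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param namespace One of `"hgnc_symbol"`, `"entrez"`, `"ensembl"`.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `namespace` attribute).
#' @export
expression_matrix <- function(values, namespace = "hgnc_symbol") {
  namespace <- match.arg(namespace, .NAMESPACES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers after collapsing", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA", call. = FALSE)
  structure(values, namespace = namespace, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "namespace")))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, namespace = attr(x, "namespace"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

.sniff_delim <- function(header) {
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read a delimited expression matrix
#'
#' Reads the layout used throughout: a header row of sample identifiers and
#' one row per gene, the first column holding the gene identifier. Duplicate
#' gene rows are collapsed by keeping the row with the largest row sum (ties
#' keep the first occurrence), the usual expression-collapse convention.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter `"tab"`, `"comma"`, or `"auto"` (sniffed from the header
#'   line by comparing tab and comma counts).
#' @param id_type Identifier namespace of column 1; see [expression_matrix()].
#' @return An `expr_matrix`. The number of duplicate rows dropped is attached
#'   as attribute `"n_collapsed"` and reported via `message()`.
#' @export
read_expression <- function(path, delimiter = c("auto", "tab", "comma"),
                            id_type = "hgnc_symbol") {
  delimiter <- match.arg(delimiter)
  id_type <- match.arg(id_type, .NAMESPACES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(delimiter, tab = "\t", comma = ",",
                auto = .sniff_delim(readLines(path, n = 1L)))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression matrix in ", path, call. = FALSE)
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", "", "NaN"))
    if (length(bad))
      stop(sprintf("unparseable value '%s' at gene row %d, sample column '%s'",
                   col[bad[1L]], bad[1L], sample_ids[j]), call. = FALSE)
    vals[, j] <- num
  }
  rownames(vals) <- gene_ids
  vals <- .collapse_duplicate_genes(vals)
  expression_matrix(vals, namespace = id_type)
}

# keep, per duplicated gene id, the row with the largest total signal
.collapse_duplicate_genes <- function(vals) {
  ids <- rownames(vals)
  n_dup <- sum(duplicated(ids))
  if (n_dup == 0L) {
    attr(vals, "n_collapsed") <- 0L
    return(vals)
  }
  totals <- rowSums(vals, na.rm = TRUE)
  ord <- order(-totals, seq_along(ids))  # best first, earlier row wins ties
  keep_first <- ord[!duplicated(ids[ord])]
  keep <- sort(keep_first)               # preserve original file order
  message(sprintf("collapsed %d duplicate gene row(s)", n_dup))
  out <- vals[keep, , drop = FALSE]
  attr(out, "n_collapsed") <- n_dup
  out
}

#' Read a gene-identifier mapping table
#'
#' Expects delimited text with a header naming (at least) the columns
#' `hgnc_symbol`, `entrez`, `ensembl`. Within each column the non-missing
#' entries must be unique.
#'
#' @param path Path to the table.
#' @param provenance Free-text description of where the table came from.
#' @return A `data.frame` of class `id_mapping_table`.
#' @export
read_id_mapping <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_delim(readLines(path, n = 1L))
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE)
  id_mapping_table(tab, provenance = provenance)
}

#' @rdname read_id_mapping
#' @param table A data.frame with the three namespace columns.
#' @export
id_mapping_table <- function(table, provenance = "user-supplied") {
  miss <- setdiff(.NAMESPACES, colnames(table))
  if (length(miss))
    stop("mapping table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (ns in .NAMESPACES) {
    v <- table[[ns]]
    v[v == ""] <- NA_character_
    table[[ns]] <- v
    dup <- duplicated(v) & !is.na(v)
    if (any(dup))
      stop("duplicate ", ns, " entries in mapping table: ",
           paste(unique(v[dup]), collapse = ", "), call. = FALSE)
  }
  structure(table, provenance = provenance,
            class = c("id_mapping_table", "data.frame"))
}

#' Translate the gene identifiers of an expression matrix
#'
#' Ensembl identifiers are version-stripped (`ENSG00000141510.11` ->
#' `ENSG00000141510`) before lookup, so annotation version drift does not
#' silently drop genes. Genes with no mapping are dropped and counted; if two
#' source genes map to the same target, rows are collapsed by the same
#' largest-row-sum rule used at read time.
#'
#' @param m An `expr_matrix`.
#' @param table An `id_mapping_table`.
#' @param target Target namespace.
#' @return An `expr_matrix` in the target namespace, with attribute
#'   `"n_dropped"` giving the number of unmapped genes.
#' @export
map_gene_ids <- function(m, table, target) {
  target <- match.arg(target, .NAMESPACES)
  stopifnot(inherits(m, "expr_matrix"))
  source <- attr(m, "namespace")
  if (source == target) {
    attr(m, "n_dropped") <- 0L
    return(m)
  }
  if (!inherits(table, "id_mapping_table"))
    stop("`table` must be an id_mapping_table", call. = FALSE)
  if (!target %in% colnames(table))
    stop("target namespace '", target, "' absent from mapping table",
         call. = FALSE)
  ids <- rownames(m)
  key <- if (source == "ensembl") sub("\\.\\d+$", "", ids) else ids
  lut_key <- table[[source]]
  if (source == "ensembl") lut_key <- sub("\\.\\d+$", "", lut_key)
  hit <- match(key, lut_key)
  mapped <- table[[target]][hit]
  keep <- !is.na(mapped)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("dropped %d gene(s) with no %s mapping", n_dropped, target))
  if (!any(keep)) stop("no genes could be mapped to ", target, call. = FALSE)
  vals <- unclass(m)[keep, , drop = FALSE]
  attr(vals, "namespace") <- NULL
  rownames(vals) <- mapped[keep]
  vals <- .collapse_duplicate_genes(vals)
  out <- expression_matrix(vals, namespace = target)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Construct a signature collection
#'
#' @param signatures Named list of character vectors of gene identifiers.
#' @param namespace Identifier namespace shared by all signatures.
#' @return An object of class `signature_collection`.
#' @export
signature_collection <- function(signatures, namespace = "hgnc_symbol") {
  namespace <- match.arg(namespace, .NAMESPACES)
  if (!is.list(signatures) || length(signatures) == 0L)
    stop("`signatures` must be a non-empty named list", call. = FALSE)
  nms <- names(signatures)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("signature names must be present and unique", call. = FALSE)
  signatures <- lapply(signatures, function(g) unique(as.character(g)))
  if (any(lengths(signatures) == 0L))
    stop("every signature must contain at least one gene", call. = FALSE)
  structure(signatures, namespace = namespace, class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("<signature_collection> %d signatures, panel of %d genes [%s]\n",
              length(x), length(panel(x)), attr(x, "namespace")))
  invisible(x)
}

#' Gene panel of a signature collection
#'
#' The panel is the union of all signature gene sets, in first-appearance
#' order; it fixes the row space to which expression input is subsetted.
#'
#' @param s A `signature_collection`.
#' @return Character vector of gene identifiers.
#' @export
panel <- function(s) {
  stopifnot(inherits(s, "signature_collection"))
  unique(unlist(s, use.names = FALSE))
}

#' Read gene signatures from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param namespace Identifier namespace of the listed genes.
#' @return A `signature_collection` with sets in file order.
#' @export
read_signatures_gmt <- function(path, namespace = "hgnc_symbol") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("GMT format error: file is empty", call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields", i),
           call. = FALSE)
    nms[i] <- f[1L]
    sets[[i]] <- f[-(1:2)][nzchar(f[-(1:2)])]
  }
  names(sets) <- nms
  signature_collection(sets, namespace = namespace)
}

#' Write a signature collection as GMT
#'
#' @param s A `signature_collection`.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_signatures_gmt <- function(s, path, descriptions = names(s)) {
  stopifnot(inherits(s, "signature_collection"))
  lines <- vapply(seq_along(s), function(i)
    paste(c(names(s)[i], descriptions[i], s[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict an expression matrix to a signature panel
#'
#' Output rows follow the panel order exactly; panel genes absent from the
#' input are retained as all-`NA` rows so the feature dimension downstream is
#' fixed. Coverage (fraction of panel genes present) is attached and checked
#' against a floor that guards against a wrong `id_type` choice.
#'
#' @param m An `expr_matrix`.
#' @param s A `signature_collection` in the same namespace.
#' @param min_coverage Minimum panel coverage accepted (default 0.6).
#' @return An `expr_matrix` with `length(panel(s))` rows and attribute
#'   `"coverage"`.
#' @export
subset_to_panel <- function(m, s, min_coverage = 0.6) {
  stopifnot(inherits(m, "expr_matrix"), inherits(s, "signature_collection"))
  if (attr(m, "namespace") != attr(s, "namespace"))
    stop("namespace mismatch: matrix is ", attr(m, "namespace"),
         ", signatures are ", attr(s, "namespace"), call. = FALSE)
  pg <- panel(s)
  idx <- match(pg, rownames(m))
  coverage <- mean(!is.na(idx))
  if (coverage < min_coverage)
    stop(sprintf(paste0("panel coverage %.2f below floor %.2f: check that the ",
                        "gene id_type matches the signature namespace"),
                 coverage, min_coverage), call. = FALSE)
  vals <- matrix(NA_real_, length(pg), ncol(m),
                 dimnames = list(pg, colnames(m)))
  vals[!is.na(idx), ] <- unclass(m)[idx[!is.na(idx)], , drop = FALSE]
  out <- expression_matrix(vals, namespace = attr(m, "namespace"))
  attr(out, "coverage") <- coverage
  out
}
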
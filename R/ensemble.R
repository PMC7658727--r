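# Two-stage gradient-boosting classifier: an ensemble of XGBoost members,
# each trained on a random subset of samples and features, whose averaged
# class probabilities are refined by an XGBoost meta-classifier that emits
# the best call. Members see missing features natively (xgboost handles NA),
# so single-sample inputs with absent panel genes still classify.

MODEL_FORMAT <- "immunesubtyper_model/1"

#' Training configuration for the subtype ensemble
#'
#' @param n_members Number of ensemble members.
#' @param sample_frac Fraction of training samples drawn (without
#'   replacement) for each member.
#' @param feature_frac Fraction of feature columns drawn for each member.
#' @param nrounds,max_depth,eta Boosting rounds, tree depth, and learning
#'   rate for the members.
#' @param meta_nrounds,meta_max_depth Boosting rounds and depth for the
#'   meta-classifier over aggregated probabilities.
#' @param seed Master seed; per-member seeds are derived as `seed + i`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(n_members = 10L, sample_frac = 0.7,
                            feature_frac = 0.7, nrounds = 30L, max_depth = 3L,
                            eta = 0.3, meta_nrounds = 20L, meta_max_depth = 2L,
                            seed = 42L) {
  if (n_members < 1L) stop("n_members must be >= 1", call. = FALSE)
  if (sample_frac <= 0 || sample_frac > 1) stop("sample_frac in (0, 1]", call. = FALSE)
  if (feature_frac <= 0 || feature_frac > 1) stop("feature_frac in (0, 1]", call. = FALSE)
  structure(list(n_members = as.integer(n_members),
                 sample_frac = sample_frac, feature_frac = feature_frac,
                 nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, meta_nrounds = as.integer(meta_nrounds),
                 meta_max_depth = as.integer(meta_max_depth),
                 seed = as.integer(seed)),
            class = "training_config")
}

.xgb_params <- function(n_class, max_depth, eta, seed) {
  list(objective = "multi:softprob", num_class = n_class,
       max_depth = max_depth, eta = eta, nthread = 1L, seed = seed,
       tree_method = "hist")
}

.xgb_probs <- function(raw, X) {
  bst <- xgboost::xgb.load.raw(raw)
  p <- predict(bst, xgboost::xgb.DMatrix(X, nthread = 1L))
  matrix(p, nrow = nrow(X), byrow = !is.matrix(p))
}

#' Train the two-stage subtype classifier
#'
#' Member `i` is fitted on a seeded random `sample_frac` of the samples and
#' `feature_frac` of the feature columns. The meta-classifier is trained on
#' out-of-bag aggregated probabilities: each training sample is scored only
#' by the members whose subsample excluded it (standard stacking hygiene;
#' samples that every member saw fall back to the all-member aggregate).
#' Fully reproducible from `(cfg, X, y)`.
#'
#' @param X Numeric samples x features matrix (e.g. from
#'   [build_feature_matrix()]); `NA` entries allowed.
#' @param y Vector of subtype labels, one per row of `X`.
#' @param cfg A [training_config()].
#' @return An object of class `subtype_model`.
#' @export
train_ensemble <- function(X, y, cfg = training_config()) {
  stopifnot(is.matrix(X), inherits(cfg, "training_config"))
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  label_names <- sort(unique(y))
  K <- length(label_names)
  if (K < 2L) stop("need at least 2 distinct labels", call. = FALSE)
  tab <- table(y)
  if (any(tab < 5L))
    stop("every label needs >= 5 samples; short: ",
         paste(names(tab)[tab < 5L], collapse = ", "), call. = FALSE)
  yi <- match(y, label_names) - 1L
  n <- nrow(X)
  n_sub <- max(1L, round(cfg$sample_frac * n))
  n_feat <- max(1L, round(cfg$feature_frac * ncol(X)))

  members <- vector("list", cfg$n_members)
  oob_sum <- matrix(0, n, K)
  oob_cnt <- integer(n)
  for (i in seq_len(cfg$n_members)) {
    seed_i <- cfg$seed + i
    set.seed(seed_i)
    rows <- sort(sample.int(n, n_sub))
    cols <- sort(sample.int(ncol(X), n_feat))
    if (length(unique(yi[rows])) < K)
      stop("a class vanished from member ", i,
           "'s subsample; increase sample_frac or cohort size", call. = FALSE)
    d <- xgboost::xgb.DMatrix(X[rows, cols, drop = FALSE], label = yi[rows],
                              nthread = 1L)
    bst <- xgboost::xgb.train(
      params = .xgb_params(K, cfg$max_depth, cfg$eta, seed_i),
      data = d, nrounds = cfg$nrounds, verbose = 0)
    members[[i]] <- list(raw = xgboost::xgb.save.raw(bst, raw_format = "ubj"),
                         features = colnames(X)[cols], rows = rows,
                         seed = seed_i)
    out <- setdiff(seq_len(n), rows)
    if (length(out)) {
      oob_sum[out, ] <- oob_sum[out, ] +
        .xgb_probs(members[[i]]$raw, X[out, cols, drop = FALSE])
      oob_cnt[out] <- oob_cnt[out] + 1L
    }
  }

  # aggregated probabilities feeding the meta stage
  agg <- matrix(NA_real_, n, K)
  seen <- oob_cnt > 0L
  agg[seen, ] <- oob_sum[seen, , drop = FALSE] / oob_cnt[seen]
  if (any(!seen)) {
    all_p <- .member_aggregate(members, X[!seen, , drop = FALSE], K)
    agg[!seen, ] <- all_p
  }
  agg <- agg / rowSums(agg)
  d_meta <- xgboost::xgb.DMatrix(agg, label = yi, nthread = 1L)
  meta <- xgboost::xgb.train(
    params = .xgb_params(K, cfg$meta_max_depth, cfg$eta, cfg$seed),
    data = d_meta, nrounds = cfg$meta_nrounds, verbose = 0)

  structure(list(format = MODEL_FORMAT, members = members,
                 meta_raw = xgboost::xgb.save.raw(meta, raw_format = "ubj"),
                 n_subtypes = K, label_names = label_names,
                 aggregate = "mean", cfg = cfg, spec = NULL),
            class = "subtype_model")
}

#' Attach the feature spec a model was trained with
#'
#' The spec travels inside the model archive so prediction can rebuild the
#' exact feature layout from raw expression.
#'
#' @param model A `subtype_model`.
#' @param spec The [feature_spec()] used to build the training features.
#' @return The model with `$spec` set.
#' @export
set_model_spec <- function(model, spec) {
  stopifnot(inherits(model, "subtype_model"), inherits(spec, "feature_spec"))
  model$spec <- spec
  model
}

#' Fit a subtype model straight from expression and labels
#'
#' Convenience wrapper: builds the [feature_spec()] and feature matrix, then
#' calls [train_ensemble()] and attaches the spec.
#'
#' @param m An `expr_matrix` of the labeled cohort.
#' @param labels Data frame with columns `sample_id`, `subtype`, or a named
#'   vector of subtypes.
#' @param signatures A [signature_collection()].
#' @param cfg A [training_config()].
#' @param pair_mode Passed to [feature_spec()].
#' @return A `subtype_model` ready for [predict.subtype_model()].
#' @export
fit_subtype_model <- function(m, labels, signatures, cfg = training_config(),
                              pair_mode = "auto") {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  } else lab <- labels
  orphans <- setdiff(colnames(m), names(lab))
  if (length(orphans))
    stop("samples without labels: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  spec <- feature_spec(signatures, pair_mode = pair_mode)
  X <- build_feature_matrix(m, spec)
  set_model_spec(train_ensemble(X, lab[rownames(X)], cfg), spec)
}

#' Aggregate per-member probability vectors
#'
#' The combination rule applied before the meta stage: arithmetic mean of the
#' member probability vectors, renormalized to sum exactly to 1.
#'
#' @param per_member_probs List of numeric probability vectors of equal
#'   length, each summing to 1 (within 1e-6).
#' @return A single probability vector.
#' @export
aggregate_members <- function(per_member_probs) {
  if (length(per_member_probs) == 0L)
    stop("no member probabilities to aggregate", call. = FALSE)
  len <- unique(lengths(per_member_probs))
  if (length(len) != 1L)
    stop("member probability vectors differ in length", call. = FALSE)
  for (p in per_member_probs)
    if (abs(sum(p) - 1) > 1e-6)
      stop("member probability vector does not sum to 1", call. = FALSE)
  m <- colMeans(do.call(rbind, per_member_probs))
  m / sum(m)
}

.member_aggregate <- function(members, X, K) {
  acc <- matrix(0, nrow(X), K)
  for (mem in members)
    acc <- acc + .xgb_probs(mem$raw, X[, mem$features, drop = FALSE])
  acc <- acc / length(members)
  acc / rowSums(acc)
}

#' Classify samples with a trained subtype model
#'
#' For each sample: build the rank-based features, score every member on its
#' feature subset, average the member probabilities, and let the
#' meta-classifier produce the final probability vector; the best call is its
#' argmax (ties go to the lowest label index). Samples whose per-sample panel
#' coverage falls below `min_coverage` are reported with `NA` results and an
#' entry in the `"errors"` attribute; the remaining samples still classify.
#'
#' @param object A `subtype_model` with its feature spec attached.
#' @param m An `expr_matrix` of samples to classify.
#' @param min_coverage Minimum per-sample fraction of panel genes observed.
#' @param ... Unused.
#' @return A `data.frame` with columns `sample_id`, `best_call`,
#'   `prob_<label>` for each subtype, and `score_<signature>` for each
#'   signature, rows in input-sample order.
#' @export
predict.subtype_model <- function(object, m, min_coverage = 0.6, ...) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(object$spec))
    stop("model has no feature spec attached; use fit_subtype_model() or set_model_spec()",
         call. = FALSE)
  spec <- object$spec
  sub <- subset_to_panel(m, spec$signatures, min_coverage = min_coverage)
  per_sample_cov <- colMeans(!is.na(unclass(sub)))
  ok <- per_sample_cov >= min_coverage
  errors <- stats::setNames(
    sprintf("panel coverage %.2f below %.2f", per_sample_cov[!ok], min_coverage),
    colnames(sub)[!ok])
  K <- object$n_subtypes
  S <- length(spec$signatures)
  probs <- matrix(NA_real_, ncol(m), K,
                  dimnames = list(colnames(m), paste0("prob_", object$label_names)))
  scores <- matrix(NA_real_, ncol(m), S,
                   dimnames = list(colnames(m), paste0("score_", names(spec$signatures))))
  best <- rep(NA_character_, ncol(m))
  if (any(ok)) {
    X <- build_feature_matrix(sub[, ok, drop = FALSE], spec,
                              min_coverage = min_coverage)
    agg <- .member_aggregate(object$members, X, K)
    meta_p <- .xgb_probs(object$meta_raw, agg)
    meta_p <- meta_p / rowSums(meta_p)
    probs[ok, ] <- meta_p
    scores[ok, ] <- X[, paste0("ss_", names(spec$signatures)), drop = FALSE]
    best[ok] <- object$label_names[max.col(meta_p, ties.method = "first")]
  }
  out <- data.frame(sample_id = colnames(m), best_call = best,
                    probs, scores, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "errors") <- errors
  out
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %d members + meta, %d subtypes (%s)%s\n",
              length(x$members), x$n_subtypes,
              paste(x$label_names, collapse = ", "),
              if (is.null(x$spec)) " [no feature spec]" else ""))
  invisible(x)
}

#' Save / load a subtype model archive
#'
#' The archive is a single versioned file containing the serialized members,
#' the meta-classifier, the feature spec, label names, and the training
#' configuration (seeds included). A loaded model predicts identically to the
#' one saved; a file in a different or unrecognized format is refused rather
#' than silently reinterpreted.
#'
#' @param model A `subtype_model`.
#' @param path File path for the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `subtype_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable model archive: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$format))
    stop("not a subtype model archive", call. = FALSE)
  if (!identical(obj$format, MODEL_FORMAT))
    stop("model archive format '", obj$format, "' does not match '",
         MODEL_FORMAT, "'", call. = FALSE)
  class(obj) <- "subtype_model"
  obj
}
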
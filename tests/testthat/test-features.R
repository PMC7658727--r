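# Rank-based feature families: quartile bins, gene-pair bits,
# signature-pair scores, signature scores.

toy_sigs <- signature_collection(list(up = c("A", "B", "C"),
                                      dn = c("D", "E", "F")))
toy_spec <- feature_spec(toy_sigs)

test_that("quartile bins follow min-rank percentiles with ties going down", {
  g <- sprintf("G%d", 1:8)
  sigs <- signature_collection(list(s1 = g[1:4], s2 = g[5:8]))
  spec <- feature_spec(sigs)
  v <- stats::setNames(as.numeric(1:8), g)
  expect_equal(unname(quartile_features(v, spec)), c(1, 1, 2, 2, 3, 3, 4, 4))
  # permuted values bin by value, not by position
  vp <- v[sample(g)]
  expect_equal(quartile_features(vp, spec)[g], quartile_features(v, spec)[g])
  # an all-tied sample sits entirely in the lowest bin
  expect_true(all(quartile_features(stats::setNames(rep(3, 8), g), spec) == 1))
  # missing genes carry a missing bin; too few observed genes error out
  v[2] <- NA
  expect_true(is.na(quartile_features(v, spec)[["G2"]]))
  v[2:6] <- NA
  expect_error(quartile_features(v, spec), "at least 4")
})

test_that("quartile bins are non-decreasing in value and monotone-invariant", {
  g <- sprintf("G%d", 1:40)
  sigs <- signature_collection(list(s1 = g[1:20], s2 = g[21:40]))
  spec <- feature_spec(sigs)
  set.seed(42)
  for (rep in 1:20) {
    v <- stats::setNames(stats::rlnorm(40), g)
    b <- quartile_features(v, spec)
    expect_true(all(diff(b[order(v)]) >= 0))
    expect_identical(quartile_features(log1p(v), spec), b)
    expect_identical(quartile_features(2 * v + 7, spec), b)
  }
})

test_that("gene-pair bits encode strict order, ties to 0, missing to NA", {
  v <- c(A = 3, B = 2, C = 2, D = NA, E = 1, F = 0)
  bits <- gene_pair_features(v, toy_spec)
  expect_equal(bits[["gp_A..B"]], 1)  # 3 > 2
  swapped <- gene_pair_features(c(A = 2, B = 3, v[-(1:2)]), toy_spec)
  expect_equal(swapped[["gp_A..B"]], 0)  # 2 > 3 is false
  expect_equal(bits[["gp_B..C"]], 0)  # tie -> 0
  expect_true(is.na(bits[["gp_A..D"]]))
  # monotone invariance: affine transform changes no bit
  expect_identical(gene_pair_features(2 * v + 7, toy_spec), bits)
})

test_that("signature-pair score matches the worked case and the closed ends", {
  v <- c(A = 3, B = 1, D = 2, E = 0)
  expect_equal(signature_pair_score(v, c("A", "B"), c("D", "E")), 3 / 4)
  # m == n with all-equal values: no strict inequality anywhere
  v2 <- c(A = 5, B = 5, C = 5)
  expect_equal(signature_pair_score(v2, c("A", "B", "C"), c("A", "B", "C")), 0)
  # complete dominance of disjoint sets
  v3 <- c(A = 10, B = 9, D = 1, E = 2)
  expect_equal(signature_pair_score(v3, c("A", "B"), c("D", "E")), 1)
  # no comparable pairs is an error
  expect_error(signature_pair_score(c(A = 1), "A", "A"), "k = 0")
})

test_that("signature-pair score agrees exactly with a brute-force double loop", {
  set.seed(7)
  for (trial in 1:300) {
    n_genes <- sample(10:40, 1)
    genes <- sprintf("G%d", seq_len(n_genes))
    v <- stats::setNames(sample(1:8, n_genes, replace = TRUE) + 0, genes)
    v[sample(n_genes, n_genes %/% 10)] <- NA  # some missing values
    m <- sample(genes, sample(2:8, 1))
    n <- sample(genes, sample(2:8, 1))        # may overlap m
    expected <- brute_force_sig_pair(v, m, n)
    if (is.na(expected)) {
      expect_error(signature_pair_score(v, m, n), "k = 0")
    } else {
      expect_identical(signature_pair_score(v, m, n), expected)
      expect_gte(signature_pair_score(v, m, n), 0)
      expect_lte(signature_pair_score(v, m, n), 1)
    }
  }
})

test_that("s_mn + s_nm = 1 for disjoint tie-free signatures", {
  set.seed(8)
  for (trial in 1:100) {
    genes <- sprintf("G%d", 1:20)
    v <- stats::setNames(sample(1000)[1:20] + 0, genes)  # tie-free
    m <- genes[1:8]; n <- genes[9:20]
    expect_identical(signature_pair_score(v, m, n) +
                       signature_pair_score(v, n, m), 1)
  }
})

test_that("signature scores are mean rank percentiles", {
  g <- sprintf("G%d", 1:10)
  v <- stats::setNames(as.numeric(1:10), g)
  expect_equal(signature_score(v, "G10"), 1.0)          # top gene
  expect_equal(signature_score(v, g), (10 + 1) / (2 * 10))  # whole-sample mean
  expect_identical(signature_score(exp(v), g[3:5]), signature_score(v, g[3:5]))
  expect_error(signature_score(v, c("ZZZ")), "no non-missing")
})

test_that("feature vectors assemble deterministically with the stated length", {
  set.seed(9)
  v <- stats::setNames(stats::rlnorm(6), c("A", "B", "C", "D", "E", "F"))
  fv <- build_feature_vector(v, toy_spec)
  expect_identical(fv, build_feature_vector(v, toy_spec))
  # |panel| + |pairs| + K^2 + K
  expect_length(fv, 6 + choose(6, 2) + 2^2 + 2)
  expect_identical(names(fv), toy_spec$feature_order)
  # matrix rows equal the per-sample vectors, independent of co-samples
  m <- expression_matrix(cbind(x = v, y = rev(v) + 1)[, , drop = FALSE])
  rownames(m) <- names(v)
  X <- build_feature_matrix(m, toy_spec)
  expect_equal(X["x", ], fv)
  X_perm <- build_feature_matrix(m[, c("y", "x")], toy_spec)
  expect_equal(X_perm["x", ], X["x", ])
})

test_that("pair-list selection switches from panel pairs to within-signature pairs", {
  big_sigs <- signature_collection(list(
    a = sprintf("A%03d", 1:60), b = sprintf("B%03d", 1:60)))
  spec_big <- feature_spec(big_sigs)               # panel 120 > 100
  expect_equal(nrow(spec_big$pair_list), 2 * choose(60, 2))
  spec_forced <- feature_spec(big_sigs, pair_mode = "all_panel")
  expect_equal(nrow(spec_forced$pair_list), choose(120, 2))
  expect_equal(nrow(toy_spec$pair_list), choose(6, 2))  # small panel: all pairs
})
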
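Package: immunesubtyper
Title: Normalization-Free Immune Subtype Classification of Tumor Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample classification of tumor gene-expression profiles into
    immune subtypes (C1-C6) using rank-based features that are invariant to any
    strictly increasing per-sample transform: within-sample quartile bins,
    binary gene-pair order indicators in the style of Top Scoring Pairs, and
    signature-pair scores s_mn = sum_ij(g_im > g_jn)/k computed across gene
    signatures. Features feed a two-stage gradient-boosting classifier: an
    ensemble of XGBoost members trained on random subsets of samples and
    features, whose averaged class probabilities are refined by an XGBoost
    meta-classifier that emits the best call. Includes expression-matrix and
    GMT readers, gene-identifier mapping (HGNC symbol, Entrez, Ensembl), a
    synthetic cohort generator with controllable subtype effect sizes, and a
    command-line interface for simulate/train/classify workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
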
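---
title: "Normalization-free immune subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization-free immune subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunesubtyper)
```

## The problem

Tumors can be grouped by the state of their immune microenvironment into a
small number of immune subtypes (conventionally labelled C1--C6). Assigning a
new tumor's RNA-seq profile to a subtype is complicated by the fact that
expression values depend heavily on the quantification pipeline: counts, TPM,
FPKM, different aligners, and different normalizations all place the same
sample on different numeric scales. A classifier that needs cross-sample
normalization cannot be applied to a single sample in isolation.

`immunesubtyper` sidesteps this by using only features that are functions of
the *ordering* of expression values within one sample. Any strictly
increasing per-sample transform `f` — library-size scaling, `log1p`,
rank-transformation, powers — satisfies `features(f(x)) == features(x)`
exactly, not approximately. That single algebraic property is what makes the
classifier single-sample and pipeline-robust, and it is asserted exactly
(bitwise identity) throughout the test suite.

## The feature model

Input expression is first restricted to the *panel*: the union of the gene
signatures that define the subtypes (485 genes across 5 signatures in the
reference setting; the package treats the collection as input). Three feature
families are computed per sample:

1. **Quartile bins.** Each observed panel gene is assigned an ordinal bin
   1--4 from its within-sample rank percentile at thresholds
   0.25/0.5/0.75. Percentiles are computed from min-ranks within tie groups
   and a percentile exactly on a threshold goes to the lower bin, so tied
   genes share a bin and an all-tied sample sits entirely in bin 1. This
   "ties-down" rule is the deterministic tie policy; any rule that depends
   on input order or on average ranks straddling a threshold would break
   reproducibility across platforms.

2. **Binary gene pairs** (Top Scoring Pairs encoding). For a fixed list of
   gene pairs `(i, j)`, the feature is `1` if `g_i > g_j` strictly, `0`
   otherwise (ties give 0), `NA` if either value is missing. Strictness is
   chosen for determinism; the consequence, documented and tested, is that
   the complementary relation `bit(i,j) + bit(j,i) = 1` holds only for
   tie-free values.

3. **Signature-pair scores.** For signatures `m` and `n`,
   `s_mn = sum_ij (g_im > g_jn) / k` over all ordered cross pairs of a gene
   from `m` against a gene from `n`, with `k` the number of pairs compared,
   so `s_mn` lies in `[0, 1]`. Pairs where the two genes are the same gene
   (signatures may share genes) are excluded from `k`: `g > g` is vacuously
   false and counting such pairs would bias the score toward 0. Pairs
   involving a missing value are likewise dropped with `k` reduced, which
   keeps the score meaningful for incomplete panels without imputation. The
   implementation is verified against an independent brute-force double loop
   on a thousand random instances.

A fourth block, per-signature **scores**, is reported alongside the
classifications: the mean within-sample rank percentile (average-rank ties,
percentile = rank / number of observed genes) of a signature's genes. The
reference method reports signature scores without defining them; the
rank-percentile mean is this package's choice, selected because it is
monotone-invariant like everything else and directly interpretable as "how
high the signature sits in this sample" on `(0, 1]`.

### Which gene pairs?

The pair family is in principle all `485 x 484` ordered pairs, which is
too many features for comfort and is not pinned down by the reference
description. The package fixes the pair list in the `feature_spec`: all
unordered panel pairs when the panel has at most 100 genes (the synthetic
regime), otherwise the pairs induced within each signature. Unordered pairs
lose no information because `g_i > g_j` determines `g_j > g_i` up to ties.
The choice is recorded in the spec object and travels inside saved models,
so a model always rebuilds exactly the features it was trained on.

### Missing data

Panel genes absent from an input matrix are kept as explicit missing rows
rather than dropped, so the feature dimension is fixed and models transfer
across datasets with different gene coverage. Missing quartile and pair
features are passed as `NA` to the gradient-boosted trees, which route
missing values natively. A coverage floor (default 0.6 of the panel,
checked both per matrix and per sample) guards against the most common
failure mode — a mismatched gene-identifier type — and refuses to classify
rather than emit garbage; below-floor samples are reported individually
while the rest of the cohort still classifies.

## The two-stage classifier

Stage one is an ensemble of multiclass gradient-boosted tree learners
(XGBoost). Member `i` is trained on a seeded random `sample_frac` of the
training samples and `feature_frac` of the feature columns (defaults 0.7 and
0.7, 10 members, depth-3 trees, 30 rounds, learning rate 0.3 — small enough
to train in seconds at desk scale while keeping the random-subspace
structure). Member probability vectors are combined by their arithmetic
mean, renormalized; the mean is the package's choice of aggregation rule and
is exposed in the configuration.

Stage two, the meta-classifier, is a second gradient-boosted learner over
the aggregated K-vector of subtype probabilities, and its argmax is the
**best call** (ties break to the lowest label index, for determinism). To
avoid training the meta stage on leaked in-bag probabilities, each training
sample is scored only by the members whose subsample excluded it
(out-of-bag stacking); a sample that every member happened to see falls
back to the all-member aggregate. With the default 10 members at 0.7
sampling, about 97% of samples have at least one out-of-bag member.

Everything is reproducible from the master seed: per-member seeds are
derived as `seed + i` and drive both the subsampling and the XGBoost fits
(single-threaded histogram trees), so two runs with equal seeds produce
byte-identical prediction tables.

## The synthetic cohort generator

Real subtype-labelled training data (the TCGA cohort behind the reference
model) is deliberately out of scope, so the package ships a generator that
creates the *structure* the features are designed to detect. Gene `g` has a
baseline log-expression drawn `N(4, 1)`; samples of subtype `k` add
`effect_size` to the log-expression of signature-`k` genes; `N(0, noise_sd)`
noise is added per value and the result exponentiated. Signatures map 1:1
to subtypes and are disjoint by default, with an `overlap_genes` option to
exercise the shared-gene path of the signature-pair score.

Default conditions: 6 subtypes, 20 genes per signature, 200 background
genes, 100 samples per subtype, `effect_size = 2` (about `e^2`-fold at the
median), `noise_sd = 1`. At these settings a model trained on a stratified
70% split recovers at least 95% of held-out labels, and at `effect_size = 0`
held-out accuracy sits at the 1/6 chance floor — both checked in the test
suite at exactly these sizes. The `monotone_distort` families (per-sample
random affine, `log1p`, power, rank maps) stand in for running the same
samples through different quantification pipelines.

What the generator does *not* emulate: count-level sampling noise, tumor
purity gradients, batch structure, correlated co-expression modules, or
realistic signature overlap. Passing tests demonstrate that the machinery is
correct and that rank-separable structure is recovered; they do not certify
accuracy on real tumors, which depends on signatures and training data the
user supplies.

## Numerical and design notes

- **Duplicate gene rows** at read time collapse to the row with the largest
  row-sum (ties keep the first occurrence) — the common expression-collapse
  convention, and deterministic.
- **Ensembl versions** (`ENSG….11`) are stripped before mapping-table
  lookup so annotation drift does not silently drop genes; unmapped genes
  are dropped with a reported count.
- **Probability vectors** are renormalized after both aggregation and the
  meta stage, so every emitted vector sums to 1 within 1e-6 (in practice
  exactly, to double precision).
- **Problem sizes** used by the shipped checks: 1,000 random instances for
  the brute-force and antisymmetry properties, a 200-sample cohort for the
  invariance property, and the 600-sample default cohort for label
  recovery — all chosen to run on one CPU in seconds while leaving the
  statistical conclusions unambiguous.
- The command-line surface (`simulate`, `train`, `classify`) writes CSV,
  JSON, and a PNG barplot only; spreadsheet and PDF exports are non-goals.

## Known limitations

- Monotone invariance is exact only up to ties created by a transform; the
  shipped distortion families are strictly increasing, and discreteness in
  user data (e.g. low counts) can create ties that perturb pair bits.
- The out-of-bag stacking protocol needs enough members for out-of-bag
  coverage; with one member the meta stage trains on in-bag probabilities
  (the degenerate single-learner configuration).
- No attempt is made to reproduce the original TCGA-trained weights; calls
  on real tumors from a user-trained model depend entirely on the user's
  training cohort and signatures.
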
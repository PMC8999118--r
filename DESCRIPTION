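Package: scSPaC
Title: Self-Paced Nonnegative Matrix Factorization Clustering for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering of single-cell RNA-seq count matrices by self-paced
    nonnegative matrix factorization. Cells enter the factorization from
    "easy" (low reconstruction loss) to "hard" under a self-paced learning
    controller with hard or mixture sample weighting, using either the
    Frobenius-norm (scSPaC) or the l2,1-norm (sscSPaC) data-fit term;
    cluster assignments come from K-means on the learned cell embedding.
    Includes the accompanying preprocessing pipeline (gene filtering,
    highly variable gene selection, log transform and per-gene scaling),
    clustering evaluation metrics (adjusted Rand index, purity, normalized
    mutual information), a gamma-Poisson count simulator with group
    differential expression and dropout for offline benchmarking, and
    readers/writers for dense and MatrixMarket count matrix formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
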
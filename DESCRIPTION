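Package: varmodnet
Title: Intragenic Variant Modules from Association-Network Representation Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate functional modules of genomic variants within
    genes from a binary patient-by-variant carrier matrix and a binary
    phenotype. Builds per-gene phenotype-conditional co-occurrence networks
    (log-ratio of case vs control Jaccard similarities), learns variant
    embeddings with three interchangeable backends (weighted random walks plus
    SkipGram, PCA, and non-negative matrix factorization), clusters embeddings
    with silhouette-selected agglomerative clustering, scores each module's
    phenotype association with a one-sided Fisher's exact test on module
    activation status, and benchmarks train/test reproducibility of every
    approach against single-variant and whole-gene controls. Includes a
    synthetic-cohort generator with planted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
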
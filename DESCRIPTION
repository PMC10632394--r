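Package: grniv
Title: Causal Gene Regulatory Network Inference with Genetic Instrumental Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide inference of directed (possibly cyclic) gene
    regulatory networks from paired expression and genotype data. Cis genetic
    variants are screened as instrumental variables per gene (marginal scans
    for common variants, a data-adaptive permutation burden test for low-MAF
    and rare variants, decorrelated top-k selection), regulatory effects are
    estimated by two-stage penalized least squares (iterative sure
    independence screening plus ridge regression with generalized
    cross-validation in stage one, adaptive LASSO on residual-projected data
    in stage two), edge confidence is quantified by bootstrap aggregation of
    adjacency indicators, and the thresholded network is partitioned into
    subnetworks by greedy modularity optimization. A structural-equation-model
    simulator generates fully specified synthetic datasets (genotypes at
    chosen minor-allele-frequency strata, cis effects, sparse cyclic
    regulation, negative-binomial count rendering) so every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    methods,
    tools,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    parallel
Suggests:
    testthat (>= 3.0.0),
    MASS,
    edgeR,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
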
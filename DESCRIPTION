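Package: pleioscan
Title: Dissecting Genetic Correlation into Pleiotropic Genes and Regulatory Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing the genetic correlation between a focal complex
    trait and a panel of endophenotypes down to genes and regulatory variants,
    using GWAS and cis-eQTL summary statistics. Implements cross-trait LD score
    regression with block-jackknife errors and a partitioned (annotation-
    stratified) genetic covariance with a Monte Carlo enrichment test;
    summary-based Mendelian randomization with an approximate posterior
    probability of association and the HEIDI heterogeneity test; a circular
    permutation test for gene-set overlap that preserves genomic clustering;
    elastic-net prediction of genetically regulated expression with holdout
    filtering and individual-level association testing; sum-of-single-effects
    fine-mapping of summary statistics, pairwise colocalization of decomposed
    signals, trait-network assembly with clique detection, and credible-set
    intersection; gapped k-mer sequence models of chromatin accessibility with
    delta scoring of variants; and position-weight-matrix motif disruption
    calls. A synthetic-data module generates LD-structured genotypes,
    genetically correlated trait pairs, cis-expression and motif-embedded peak
    sequences with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    e1071
Config/testthat/edition: 3
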
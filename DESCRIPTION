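Package: ldpgs
Title: Polygenic Scores from GWAS Summary Statistics with Sparse LD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives polygenic scores from GWAS summary statistics and a
    windowed sparse linkage-disequilibrium (LD) matrix using a spike-and-slab
    Gibbs sampler. Implements the infinitesimal analytic solver, a grid of
    (p, h2, sparse) models, and an automatic mode that learns the proportion
    of causal variants and the SNP heritability inside the sampler with
    multi-chain divergence filtering. Includes summary-statistic scaling and
    quality control, constrained LD score regression, genetic-distance
    windowed LD estimation, PLINK bed/bim/fam input and output, a
    liability-threshold-model simulation harness, and bootstrap AUC
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
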
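Package: csprs
Title: Polygenic Scoring with Continuous Shrinkage Priors from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference of posterior SNP effect sizes from
    genome-wide association summary statistics under a continuous
    shrinkage (global-local scale mixture of normals) prior, using a
    Gibbs sampler with multivariate updates of effect sizes within
    linkage-disequilibrium blocks and an optional fully Bayesian
    half-Cauchy update of the global shrinkage scale. Includes reading
    and harmonization of summary statistics against a PLINK reference
    panel, LD-block correlation estimation on a genome partition,
    comparator methods (marginal-effect scores, LD clumping with
    p-value thresholding, and the infinitesimal-model closed form), a
    genetic-architecture simulator with block-LD genotypes and fixed
    heritability, and a polygenic-score evaluation harness with
    validation/testing tuning, Nagelkerke R-squared, AUC and
    calibration-slope metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pROC
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
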
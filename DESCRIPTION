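Package: tickblup
Title: Multi-Breed Single-Step Genomic Evaluation of Tick Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pooled, multi-country, multi-breed genomic evaluation of cattle
    tick resistance. Provides forward simulation of multi-breed populations
    (drifted founder haplotypes, composite crosses, correlated breeding
    values, repeated tick-count and score phenotypes), phenotype preparation
    (log-count transforms, 0-5 score binning, contemporary-group
    construction and trimming), sample- and marker-level genotype quality
    control, population-genomic diagnostics (adjacent-marker linkage
    disequilibrium, persistence of phase across breeds, allele-frequency
    correlations, PCA of the genomic relationship matrix), pedigree and
    genomic relationship matrices with single-step H-inverse blending,
    Bayesian variance-component estimation by Gibbs sampling with
    convergence diagnostics, multi-trait (breed-as-trait) single-step GBLUP,
    and LR-method cross-validation of genomic predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
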
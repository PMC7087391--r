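Package: bayesxii
Title: Parallelizable Gibbs Sampling for Bayesian Whole-Genome Regression
    via Orthogonal Data Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome regression with the BayesCpi spike-and-slab prior,
    fitted either by the conventional single-site Gibbs sampler (in two
    complexity variants) or by the BayesXII sampler, which augments the
    marker covariate matrix with synthetic rows so that its columns become
    mutually orthogonal and every marker effect can be drawn independently
    -- and hence in parallel -- within each step of the chain.  Includes a
    forward-in-time random-mating simulator for genotype/phenotype data
    with drift-generated linkage disequilibrium, Gelman-Rubin convergence
    diagnostics, genomic prediction accuracy measures, and a command-line
    interface tying simulation, augmentation, sampling and diagnostics
    together.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
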
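Package: paraclock
Title: Relaxed Molecular Clocks and Rate Extraction Around Ancient Gene
    Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the tempo of protein evolution around
    ancient gene duplications with Bayesian relaxed molecular clocks.
    Implements Felsenstein pruning likelihoods under empirical amino-acid
    substitution models with discrete-gamma rate heterogeneity,
    autocorrelated-lognormal and uncorrelated-gamma rate models, node
    calibrations with hard or soft bounds, and Metropolis-within-Gibbs
    sampling over node ages, branch rates and hyperparameters on a fixed
    rooted topology. Provides the duplication cross-calibration framework
    relating the time span between a gene duplication and a crown clade
    (delta-T) to the extracted maximum and minimum rates (nu_max, nu_min),
    scenario sweeps over calibration grids, power-law and
    exponential-decay fits of rate through time, corrected amino-acid
    distances with bootstrap errors, marginal ancestral sequence
    reconstruction with maximum-likelihood or parsimony indel placement,
    and a forward simulator of duplication-anchored paralog alignments for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
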
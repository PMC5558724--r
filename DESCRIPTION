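Package: hybbr
Title: Hybrid EM-MCMC BayesR for Genomic Prediction and QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic prediction and QTL mapping with the BayesR four-component
    normal-mixture model for SNP effects, fitted by three engines: GBLUP
    mixed-model equations, full Markov chain Monte Carlo (Gibbs) sampling, and
    a hybrid scheme that runs expectation-maximization to convergence and then
    a short warm-started MCMC with an SNP-exclusion speed-up. Includes builders
    for genomic (G), pedigree (A) and heterogeneous-error (E) relationship
    matrices, record weighting for daughter-trait-deviation phenotypes,
    posterior-probability QTL mapping, prediction accuracy/bias evaluation,
    and a synthetic multi-breed data simulator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
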
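Package: rmbvs
Title: Robust Marginal Bayesian Variable Selection for Gene-Environment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marginal (per-gene) Bayesian variable selection for
    gene-environment interaction studies. Implements a Gibbs sampler for the
    least-absolute-deviation (LAD) Bayesian LASSO with spike-and-slab priors
    (LADBLSS), which is robust to heavy-tailed errors and outliers in the
    phenotype, together with three comparators: the robust LAD Bayesian LASSO
    without spike-and-slab priors (LADBL), the least-squares Bayesian LASSO
    with spike-and-slab priors (BLSS) and the plain Bayesian LASSO (BL).
    Includes posterior-inclusion-probability and credible-interval selection,
    ROC/AUC and top-k evaluation against simulated truth, Gelman-Rubin
    potential scale reduction factor diagnostics, and generators for the
    simulation designs used to benchmark marginal G-by-E methods (AR1
    continuous expression, quartile-dichotomized SNPs, and SNPs under
    pairwise linkage disequilibrium).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
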
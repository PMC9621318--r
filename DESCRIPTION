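Package: ppkfuse
Title: Fusing Population-Pharmacokinetic Covariate Models into Machine-Learning
    Datasets for Valproic Acid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of virtual patient populations from two
    published one-compartment covariate models of valproic-acid clearance and
    distribution, fusion of the simulated cohorts into a single 16-feature
    machine-learning dataset (k-nearest-neighbour imputation, one-hot encoding,
    min-max scaling), benchmarking of tree-ensemble regressors of steady-state
    concentration, Shapley-value model interpretation with an exact
    interventional tree algorithm, and genotype-by-comedication exposure
    scenarios integrated by the trapezoidal rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    Rcpp,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
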
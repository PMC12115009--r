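Package: selfpred
Title: Genomic Prediction and Kinship Analysis for Partially Selfed Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in partially self-fertilized breeding
    populations such as Eucalyptus inbred-line programs. Builds pedigree (A),
    genomic additive (G), genomic dominance (D) and single-step hybrid (H)
    relationship matrices; fits ABLUP, GBLUP, additive-dominant GBLUP and
    HBLUP mixed models by EM-REML and five Bayesian whole-genome regressions
    (Bayesian ridge regression, BayesA, BayesB, BayesC and the Bayesian
    LASSO) by Gibbs sampling; evaluates models by winsorized 10-fold
    cross-validation with predictive capacity, mean squared error and R2;
    ranks genomic estimated breeding values of unphenotyped candidates;
    estimates linkage-disequilibrium decay; and assigns paternity with
    LOD/Delta statistics and a simulated significance threshold. A forward
    simulator of selfed/outcrossed progeny with linkage, dominance and a
    blocked field design makes the whole pipeline testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
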
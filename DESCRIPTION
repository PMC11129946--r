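Package: apf2
Title: Ensemble Prediction of Pharmacogenomic Variant Effects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking variant effect predictors on labeled
    pharmacogenomic missense variants, re-parametrizing predictor thresholds
    by maximizing Youden's J with k-fold cross-validation, aggregating the
    re-parametrized predictors into the APF2 weighted ensemble functionality
    score with a fixed deleterious cutoff, estimating quantitative enzyme
    activity from ensemble scores, and aggregating population allele
    frequencies into per-individual variant burdens and per-1000 individuals
    at-risk estimates under Hardy-Weinberg equilibrium.  Includes a
    synthetic-data generator with closed-form oracles so the full pipeline
    can be exercised without external annotation resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
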
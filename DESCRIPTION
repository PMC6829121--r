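Package: mtcv
Title: Cross-Validation for Multi-Trait Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for cross-validation of
    single- and multi-trait GBLUP genomic prediction. Simulates genetically
    and residually correlated trait pairs on a genomic relationship matrix,
    fits univariate and bivariate linear mixed models by REML, produces
    single-trait, CV1-style and CV2-style predictions of genetic values,
    and compares estimators of prediction accuracy: the naive
    phenotype-validated estimator, a parametric selection-index estimator,
    a semi-parametric bias correction, and the CV2* strategy that validates
    predictions against phenotypes of clones or close relatives. Quantifies
    when naive cross-validation misleads model selection between single-
    and multi-trait models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    yaml,
    withr
Config/testthat/edition: 3
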
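Package: rangedyn
Title: Fine-Scale Range Dynamics of Narrow Endemic Mountain Plants Under
    Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for projecting fine-scale
    range dynamics of narrow endemic mountain plants under climate change:
    pooled principal-component climate axes, geographically weighted
    regression downscaling onto topographic predictors, a five-family
    species distribution model ensemble with repeated split-sample
    validation (AUC, TSS), ROC-based binarization with majority consensus
    and a geology mask, loss/stable/gain range accounting, terrain
    heterogeneity indices (TRI, TCI), multivariate climate-change velocity
    by nearest-analog search, and category-wise nonparametric statistics
    with a randomization robustness procedure.  A synthetic-landscape
    generator with known ground truth (plateau topography, 19 correlated
    bioclimatic layers, carbonate geology mask, virtual species) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    graphics,
    mgcv,
    randomForest,
    Rcpp,
    rpart,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
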
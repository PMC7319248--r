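Package: cetsdm
Title: Cetacean Species Distribution Models from Line-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, fitting and evaluation tools for comparing
    smoother-based density models and boosted-tree habitat-suitability
    models built from systematic ship line-transect survey data. Includes
    a synthetic ocean / survey generator (daily 0.1-degree environmental
    fields, transect effort, Beaufort-dependent detection), effort
    segmentation with effective-area offsets, Tweedie count and group-size
    generalized additive models, binomial presence-absence models, boosted
    regression trees with random-variable predictor screening, gridded
    prediction composites with lognormal confidence surfaces, and a
    performance battery (explained deviance, AUC, TSS with max-SSS
    thresholding, exact stratified Spearman rank validation, novel-year
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
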
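Package: phytosize
Title: Multiscale Phytoplankton Size-Trend Analysis for Coastal Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting long-term phytoplankton miniaturization in
    monthly station-by-species biovolume monitoring records. Computes species-
    and community-level size series, the proportion of small species (Small%),
    ordinary and seasonally decomposed linear trends with Benjamini-Hochberg
    correction, Bray-Curtis/ANOSIM community-turnover tests, an exact partition
    of community mean-size change into within-species (size shift) and
    composition (species shift) components, and environmental driver
    attribution via partial effects (temperature-size rule tests), a pluggable
    learner tournament, and model-agnostic Shapley values with pairwise
    interaction indices. Includes a synthetic coastal-community generator with
    known, recoverable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    nnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
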
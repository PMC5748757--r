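Package: gutnet
Title: Detecting Weak Dietary Impacts on the Gut Ecosystem with Random
    Forests and Correlation-Network Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for finding small, masked effects of
    diet on the gut ecosystem from longitudinal multi-assay feeding
    studies (fecal and urinary metabolites, microbial taxa, urinary
    elements). Feature tables are unit-variance scaled, screened by
    random-forest mean-decrease-in-accuracy importance with
    cross-validation guards, and the top-ranked factors are overlaid
    onto communities of a Spearman correlation network obtained by
    greedy modularity maximisation; member factors of the selected
    communities are compared across treatment groups with Mann-Whitney
    tests under Holm family-wise error control. A synthetic study
    generator with planted, block-correlated treatment effects and
    per-subject random offsets provides ground truth for power and
    type-I-error evaluation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
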
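Package: hbxprof
Title: Expression Breadth and Tissue-Specificity Profiling of Homeobox Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the tissue specificity of homeobox gene
    expression from FPKM-style matrices: threshold-based expression calling,
    per-gene max-normalisation, hierarchical clustering of expression
    profiles into labelled expression groups, tissue-set exclusivity
    filtering with developmental peak-window detection, expression-breadth
    statistics summarised by evolutionary gene class, and Jaccard-turnover
    segmentation of staged developmental series into phases of gene
    activity. Includes a seeded synthetic-data generator that plants
    widespread, module-specific, reproductive-exclusive and silent
    archetypes with known truth labels, so every pipeline stage can be
    validated end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
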
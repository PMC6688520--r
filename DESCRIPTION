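Package: methcross
Title: Cross-Comparative Epigenome-Wide Differential Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-comparative epigenome-wide association studies
    (EWAS) of DNA methylation in two diseases against a shared control group.
    Provides covariate-adjusted per-CpG linear modelling with Bonferroni
    thresholds, classification of differentially methylated CpG sites (DMCs)
    into shared, disease-unique and indeterminate categories, reference-based
    estimation of blood cell-type proportions by constrained projection,
    signature multidimensional scaling with serology stratification,
    functional-region and chromatin-mark enrichment, and a nested
    cross-validated random-forest disease classifier with in-fold feature
    screening. Includes a synthetic-cohort generator with planted ground truth
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    quadprog,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
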
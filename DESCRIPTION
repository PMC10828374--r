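Package: moltclock
Title: Metabolic Aging Clocks and Population-Noise Statistics for Molted Laying Hens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying whether induced molting rejuvenates the
    plasma metabolome of aging laying hens. Implements the full analysis
    chain: a longitudinal cohort simulator (metabolite intensities, daily
    egg-laying logs, mortality, and a cytokine panel, with queryable planted
    ground truth), reproduction and survival phenotypes, FDR-controlled
    aging- and laying-biomarker screens (pairwise Mann-Whitney with an OR
    pooling rule and a median-monotonicity filter; Spearman correlation
    against monthly laying efficiency), metabolic-age models (PCA age axis
    and a control-trained random-forest regressor with leave-one-out
    evaluation and LASSO screening), and coefficient-of-variation
    population-noise statistics with hen-label and paired within-hen
    permutation tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
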
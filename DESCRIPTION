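Package: flavoqsar
Title: QSAR Modelling of Flavonoid Activity on Voltage-Gated Calcium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative structure-activity relationship
    (QSAR) analysis of flavonoid modulation of the L-type voltage-gated calcium
    (CaV) channel. Computes graph-topological molecular descriptors (Kier
    second-order kappa-alpha shape index, total and mean information content on
    graph-distance equality, moment of inertia), fits principal-components
    regression models with adjusted-r-squared-driven component selection and
    genetic-algorithm descriptor-subset search, and implements the full QSAR
    validation-metric suite (r2, adjusted r2, F, standard error, PRESS, SDEP,
    leave-one-out q2, the rm2 family, predictive r2, RMSEP). Ships the
    published flavonoid activation/inhibition data tables as fixtures,
    reproduces the recomputable printed model statistics, audits table
    arithmetic, and provides a synthetic-data generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    ChemmineR,
    generics,
    withr,
    stats,
    tools,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
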
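Package: metcor
Title: Genetic Correlation and Trend Analysis for Official Variety Trial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed models for trial-mean yield data from official
    multi-environment variety testing networks spanning several countries or
    agroecological zones. Provides a REML/ML engine for a catalogue of
    genotype-group covariance structures (identity, compound symmetry,
    unstructured, factor-analytic, random-coefficient regression and a
    Kronecker random-coefficient structure), estimation of genetic and
    non-genetic yield trends with a nitrogen covariate, BLUP prediction of
    genotype means per country or zone, model comparison by REML- and
    ML-based AIC, data-driven merging of agroecological zones, and a
    synthetic trial-system generator with ground-truth parameters for
    validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmmTMB,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
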
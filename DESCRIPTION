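Package: qsprscreen
Title: QSPR Modeling and Virtual Screening of Heavy-Metal Chemosensor Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative structure-property
    relationship (QSPR) modeling of metal-ligand complex stability constants
    (log beta) and potentiometric sensitivity (PS) towards Cd2+, Cu2+ and
    Pb2+. Implements descriptor cleaning (near-constant and collinearity
    filters), standard scaling, genetic-algorithm descriptor selection for
    multiple linear regression under the QUIK collinearity rule, a full
    internal/external validation battery (Q2 leave-one-out, leave-many-out,
    Y-randomization, Q2F1/F2/F3, Friedman lack-of-fit), leverage-based
    applicability domain assessment (Williams plot), AdaBoost.R2 boosting
    over linear base learners, a bank of six published predictive equations,
    R-group library enumeration and Pareto-consensus virtual screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
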
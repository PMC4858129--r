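Package: npiplus
Title: Nottingham Prognostic Index Plus Biological Classes and Prognostic Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-tier prognostic stratification of early-stage breast cancer.
    Tumours are first assigned to one of seven biological classes (three
    luminal, two basal, two HER2-positive) by fuzzy rule-based evaluation of a
    ten-biomarker immunohistochemistry panel scored on the H-score scale, then
    stratified within class by bespoke clinicopathological index formulae
    derived from Cox regression of breast-cancer-specific survival. Includes
    H-score computation and cut-off policies, HER2 equivocal-case handling,
    Kaplan-Meier, log-rank and Cox survival machinery, contingency-table
    association statistics (Cramer's V), a reproducible synthetic-cohort
    generator, and a validation pipeline that emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
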
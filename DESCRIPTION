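Package: protdiv
Title: Protein-Source Diversity and Amino Acid Adequacy from 24-Hour Dietary Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein nutrition in population dietary
    surveys. Aggregates single 24-hour recall records against a food
    composition table into daily energy, protein-by-source and essential
    amino acid (EAA) intakes; computes a protein-source diversity score
    (count of eight protein food categories consumed), protein adequacy
    ratios against the 0.83 g/kg/day requirement, per-EAA adequacy ratios
    and their mean (MAR); derives asset-based wealth indices (principal
    components with varimax rotation), urbanisation classes and a
    point-scored modernisation index; applies post-stratification cell
    weights; and produces survey-weighted stratified tables, one-way
    ANOVA and chi-square tests, and bivariate logistic odds ratios.
    Includes a calibrated synthetic-survey generator so the whole
    pipeline is testable without restricted microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    ggplot2,
    readr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
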
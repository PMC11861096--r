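Package: thermet
Title: Thermal Time and Genotype-by-Environment Analysis for Heat-Stress
    Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies heat stress in multi-environment field trials with
    thermal time. Computes growing degree days (GDD) and stress degree days
    (SDD, the thermal accumulation attributable to temperatures above a
    growth ceiling) over phenological stage windows; summarises environments;
    ranks genotypes by Lin-Binns cultivar superiority and static stability;
    decomposes genotype-by-environment tables with environment-centered
    singular value decomposition (GGE biplots); estimates broad-sense
    heritability from randomized complete block designs; correlates thermal
    statistics with harvest traits; and ships a fully parameterised synthetic
    multi-environment trial generator with chickpea-like phenology so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
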
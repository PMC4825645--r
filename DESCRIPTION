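Package: killiscreen
Title: Simulation and Analysis of Selfing Forward-Genetic Screens in a
    Hermaphroditic Killifish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing simultaneous
    zygotic and sterile forward-genetic screens in self-fertilizing
    hermaphroditic fish such as the mangrove killifish. Provides exact
    Mendelian selfing and survivor-conditional genotype distributions, a
    seeded multi-generation gene-drop simulator producing pedigree and
    per-embryo clutch tables, the clutch-scoring and sterility/carrier
    classification rules used in such screens (including backward
    genotyping from reared descendants), analytic detection-probability
    and cohort-size calculations comparing selfing with gonochoristic
    intercross designs, and chi-square goodness-of-fit tests for
    segregation ratios including an integer-rounded expected-count
    dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
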
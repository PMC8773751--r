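Package: scanmarkov
Title: Markov-Chain Analysis of Eye-Tracking Fixation Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling eye-tracking scanpaths as first-order Markov
    chains over areas of interest (AOIs). Reads fixation-event exports, codes
    fixations into Face / Object / No-stimulus states, estimates group
    transition matrices by maximum likelihood with standard errors and
    confidence intervals, computes stationary (steady-state) distributions
    with parametric-bootstrap intervals, tests the Markov property
    (first- versus second-order dependence) and chain homogeneity between two
    groups via a Kullback-style divergence test, and reproduces baseline
    demographic comparisons. Includes a seeded synthetic fixation-sequence
    generator emulating a two-group toddler visual-search study, plus tidy()
    and glance() methods and ggplot2 visualisations for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
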
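Package: errcohort
Title: Excess Relative Risk Models for Occupational Radiation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of occupational cohorts with prolonged
    external gamma and internal plutonium exposure. Generates synthetic worker
    cohorts with era-declining annual doses and competing-risk mortality,
    derives lagged cumulative dose covariates, exposure-window partitions and
    plutonium surrogate categories, tabulates person-years over time-dependent
    strata (Lexis splitting), and fits excess-relative-risk (ERR) Poisson rate
    models of the form rate = baseline * (1 + ERR) by maximum likelihood with
    profile-likelihood confidence intervals, likelihood-ratio tests, and
    background/excess case attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
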
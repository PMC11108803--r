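Package: bamsim
Title: Multi-State Markov Simulation of Hypertension Scenarios, Dementia and
    Disability Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time ten-state Markov cohort model of cardiovascular
    disease, cognitive impairment, dementia, disability and death for a
    population aged 35-100, with a hypertension-prevalence scenario engine
    based on the population attributable risk fraction (PARF) and the
    potential impact fraction, Poisson log-linear mortality trend
    projection, life-expectancy and Sullivan healthy-life-expectancy
    outputs, and Monte Carlo probabilistic sensitivity analysis. Includes a
    synthetic-data generator emulating the statistical structure of the
    survey and registry inputs such models are calibrated to, so the full
    pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
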
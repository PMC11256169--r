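Package: skinsim
Title: Agent-Based Simulation of Bacterial Colonization on Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lattice agent-based model of skin bacterial community dynamics
    with energy-based growth, nutrient replenishment and diffusion, and
    MIC-threshold antibiotic killing.  Provides intervention scenarios for an
    engineered Bacillus subtilis-like invader (antibiotic selection, exclusive
    carbon-source supplementation, non-specific nutrient boluses, growth
    defects), replicate experiment presets with censored invader-survival and
    steady-state composition statistics, and a fluorescence growth-curve
    toolkit (background subtraction, central-difference production-stop
    detection, log-log rate constants, mid-exponential doubling-time fits)
    with a synthetic plate-reader data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
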
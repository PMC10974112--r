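Package: rheomelt
Title: Melt Viscosity Modeling for Drug/Polymer Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring-style simulation and modeling of the melt
    viscosity of pharmaceutical drug/polymer mixtures. Implements the Carreau
    shear-thinning model coupled to Arrhenius time-temperature superposition,
    a drug shift factor covering plasticizing, filler, and mixed two-phase
    behavior, master-curve construction from multi-temperature rheometry
    sweeps, simultaneous constrained parameter estimation with replicate
    statistics, and extraction of drug-in-polymer solubility from
    temperature-resolved shift factors. A synthetic-data generator emulates
    triplicate oscillatory and rotational rheometer sweeps so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
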
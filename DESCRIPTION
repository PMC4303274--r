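Package: hemicam
Title: Hemiconcerted Two-State Allosteric Models of Calmodulin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic Monod-Wyman-Changeux (MWC) modelling of calcium
    binding to calmodulin and its tryptic lobe fragments. Each globular
    lobe is treated as a concerted two-state (T/R) unit with two identical
    calcium sites, while the two lobes of the intact protein switch
    conformation independently (a hemiconcerted scheme with four
    whole-molecule conformations RR, RT, TR, TT). The package provides
    closed-form saturation functions with allosteric target modulation,
    Hill-plane analysis, equilibrium solving from total reagent
    concentrations, combinatorial generation of the full reaction network
    with SBML export, a constrained population-based fitting protocol for
    titration curves, and a seeded synthetic titration-data generator for
    benchmarking parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
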
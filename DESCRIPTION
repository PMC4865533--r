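Package: epiboly
Title: Cellular Potts Simulation of Chemotaxis-Driven Radial Intercalation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of epiboly in the amphibian blastocoel
    roof. A cellular Potts model couples a superficial epithelial layer that
    secretes a diffusing, decaying chemoattractant to a multilayered deep
    cell population that chemotaxes toward it, producing radial
    intercalation, tissue thinning and lateral expansion. Includes elastic
    deep-superficial couplings, asynchronous midline divisions, open lateral
    boundary conditions, an in-silico experiment suite (chemotaxis
    knockouts, secretion-level sweeps, ubiquitous and localized sources,
    multilayer and depleted tissues, explant chemotaxis assays) and tidy
    morphometric quantifications (thickness, layer counts, expansion,
    intercalation directionality, chemotaxis index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
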
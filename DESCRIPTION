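Package: macronull
Title: Null-Model Macroecology of Latitudinal Richness Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for null-model analysis of species richness along a
    bounded latitudinal gradient, motivated by the freshwater mollusk
    fauna of Chile (18-56 degrees S in 1-degree bands). Builds binary
    species-by-band incidence matrices from occurrence records or
    latitudinal ranges; estimates inventory completeness (Chao2); tests
    Rapoport's rule by randomized midpoint-extent regression; simulates
    mid-domain-effect richness envelopes under geometric constraints;
    scores nestedness (NODF, matrix temperature, BR discrepancy) against
    fixed-row equiprobable-column null models; tests species co-occurrence
    (C-score) against the SIM9 fixed-fixed sequential-swap null; clusters
    bands by Jaccard similarity with UPGMA and SIMPROF significance; and
    ranks Poisson regression models of richness on environmental
    predictors by AICc. A synthetic-data generator with controllable
    range-size, nestedness and co-occurrence structure makes every stage
    testable by parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
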
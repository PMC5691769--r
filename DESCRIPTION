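Package: anemiasom
Title: Self-Organizing-Map Subtyping of Nutritional Profiles for Anemia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for subtyping nutritional and socio-economic
    profiles in prospective anemia cohorts: age-matched case-control
    construction, a sex-weighted Spearman correlation network with
    spanning-tree pruning and community modules, principal-component
    matching of an independent training set, self-organizing-map (SOM)
    subtyping with bootstrap subgroup summaries, univariate association
    machinery (age residualization, Fisher combination, false discovery
    rates), and an iron-fortified soy sauce scenario calculator. A seeded
    synthetic-cohort generator emulates the published subgroup archetypes
    so every stage is testable without access to the original survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
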
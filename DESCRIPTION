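Package: befmf
Title: Biodiversity-Ecosystem-Function Multifunctionality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for linking plant and soil microbial
    diversity to ecosystem multifunctionality: min-max standardized
    multifunctionality indices (weighted by ecosystem service and flat
    averaged), multi-threshold diversity-function slope curves, composite
    richness metrics, variation partitioning of adjusted R-squared among
    predictor groups with Freedman-Lane permutation tests, AICc-based
    multimodel averaging with predictor importance, piecewise structural
    equation modelling with d-separation basis sets and Fisher's C, aridity
    index classification, ordination-based composite covariates, and
    synthetic-data generators emulating a full-factorial
    dilution-to-extinction microcosm experiment and a global grassland
    survey so that every stage can be exercised with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
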
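Package: pinonbranch
Title: Branch-Level Drought Response of Pinyon Pine: Needle Traits, Annual
    Sapwood-to-Leaf-Area Ratios, and Climate Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a multi-year rainfall-manipulation
    experiment on Pinus edulis branches. Converts daily climate into
    hydrological-year predictors (seasonal precipitation, high-VPD day
    counts), computes needle evaporative-structure traits including the
    maximal anatomical stomatal conductance from stomatal density and
    pore geometry, derives annual sapwood-to-leaf-area ratios (SA:LA and
    SA:LA/d) from dissected-branch ring, needle, and shoot-segment
    tables, and provides the inference layer: rank-sum and
    Kolmogorov-Smirnov tests, zero-intercept regressions with bootstrap
    slope comparison, and linear mixed-effects models with standardized
    climate predictors, AIC model search, and marginal/conditional R
    squared. A treatment-structured synthetic data generator emulates the
    field experiment so every stage is testable and parameter recovery
    can be demonstrated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
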
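Package: forestcarbon
Title: Age-Cohort Simulation and Growth-Curve Projection of Forest
    Biomass Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects forest biomass carbon stocks and sinks with an
    annual age-cohort landscape simulator (1-km2 cohorts on a 0.5-degree
    grid) that represents policy-constrained timber harvest with an
    allowable-cut cap, stochastic stand mortality, survey-derived age
    accrual, provincial forestation deployment under suitability-priority
    planting, and two management interventions (harvest-rotation
    extension after the key year and species replacement).  Harvested
    carbon feeds an IPCC Tier-2 harvested-wood-product pool (sawn wood,
    wood-based panels, paper/paperboard) with first-order decay.  A
    statistical counterpart fits Richards, Korf and Hossfeld stand
    growth curves per stratum with ten-part validation and predicts via
    an R-squared-weighted ensemble.  A synthetic-data module generates
    NFI-like plot records, species parameter tables, landscapes,
    forestation plans and product-ratio series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
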
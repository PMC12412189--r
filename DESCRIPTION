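Package: aortamech
Title: Biaxial Mechanics of the Murine Aorta: HGO Model Fitting and
    Physiologic Biomechanical Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for passive biaxial inflation-extension tests
    of arteries on a pressure myograph. Computes mid-wall stretch ratios and
    average Cauchy stresses for an incompressible thick-walled cylinder, fits
    a two-fiber-family Holzapfel-Gasser-Ogden (HGO) constitutive model by
    penalized constrained regression, derives physiologic biomechanical
    metrics (stored strain energy, wall stresses with isotropic/anisotropic
    splits, incremental moduli) at group mean blood pressures, and relates
    metrics to deformed inner diameter with forward-stepwise mixed regression
    screened by variance inflation factors. Includes a forward simulator that
    generates group-structured synthetic pressure-diameter-force cohorts for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    lhs,
    lme4,
    lmerTest,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
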
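Package: cryocarbon
Title: Microbial Energetics and Organic Carbon Cycling in Cryopeg Brines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the energetic history of microbial
    communities in ancient, hydrologically isolated subzero brines
    (cryopegs).  Provides closed-form estimators of community minimum
    growth rate, cell-specific metabolic rate bounds and extracellular
    enzyme activity (EEA) rate bounds from endpoint carbon and cell-density
    measurements; a Monod-based ordinary differential equation model of the
    brine organic carbon cycle (POC, DOC, DIC and cell density) with
    pulsed carbon additions and starvation death; an eight-combination
    simulation grid over borehole scenarios; Sobol variance-based global
    sensitivity analysis with bootstrap confidence intervals; and a
    synthetic-scenario generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
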
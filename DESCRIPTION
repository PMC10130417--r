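Package: vpiq
Title: Quantitative Single-Vesicle Imaging of Vesicle-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify vesicle-protein interactions (VPIs) from
    single-vesicle TIRF microscopy. Provides a synthetic-data generator for
    surface-tethered protein fields and bound vesicles (spatial Poisson
    placement, diffraction-limited rendering with camera noise, stepwise
    photobleaching, inter-channel bleed-through), diffraction-limited spot
    detection with sub-pixel Gaussian localization, intensity-to-density
    calibration, photobleaching step counting, crosstalk-corrected
    two-channel colocalization, and closed-form adsorption models (simple
    Langmuir, density-dependent cooperation with two equilibrium constants,
    Hill, sigmoidal IC50, pseudo-first-order kinetics) with weighted
    nonlinear least-squares fitting, bootstrap uncertainty, AICc model
    selection, and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
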
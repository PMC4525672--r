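Package: bronchosim
Title: Quasi-Static Simulation of Airway Deformation and Mucus Clearance During Chest Physiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled mechanics of the human bronchial tree, the
    lung parenchyma and the thorax during chest physiotherapy maneuvers. The
    lung is an idealized 23-generation symmetric bifurcating tree whose
    conducting airways follow Lambert sigmoid pressure-area laws and whose
    acini follow reconstructed quasi-static respiratory-system pressure-volume
    curves. Airway secretions are modeled as a Bingham (yield-stress) annulus
    around a Newtonian air core; closed-form core-annular Poiseuille
    hydrodynamics map pressure gradients to air and mucus fluxes. A fully
    implicit first-order time stepper advances the coupled
    differential-algebraic system under a prescribed time-varying chest
    pressure (quiet ventilation, manual chest physiotherapy, or high-frequency
    chest wall oscillation), and scalar outcome metrics (expelled mucus
    volume, relative tree resistance, mean mucus position, Shrek efficiency
    number, comfort number) quantify each maneuver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
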
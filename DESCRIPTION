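Package: nanodrop
Title: Biophysics of Nanoliter Droplets Under Oil: Shrinkage, Viscosity and
    Sperm Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the fate of aqueous nanoliter droplets held under a
    protective oil layer, as used for single-sperm cryopreservation.
    Implements ideal spherical-cap geometry of sessile droplets, Fick's-law
    water loss into the oil with its constant surface-shrinkage rate, the
    resulting solute-concentration dynamics and their steep volume dependence,
    two independent micro-viscometry routes (Perrin fluorescence-polarization
    and volume-ratio), low-Reynolds Stokes drag of a tri-axial ellipsoid with
    constant-thrust velocity prediction, and motility/velocity/survival
    analytics including deterministic trajectory linking and Fisher's exact
    test. Seeded synthetic-data generators emulate every measurement modality
    so the full pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
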
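Package: huskmodel
Title: Hemp Seed Husk-Removal Modelling and Cannabinoid Residue Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the selective removal of delta-9-tetrahydrocannabinol (THC)
    from hemp seeds. A spherical husk/kernel shell model links the removed
    volume fraction of a seed to the density and THC concentration of the
    remaining material, and a closed-form solver finds the minimal removal
    needed to meet a regulatory THC ceiling. A mass-balance simulator of the
    oil-roasting and water-washing extraction protocol, a chromatogram
    quantification pipeline (peak detection, retention-window assignment,
    multi-level calibration, compliance verdict), and synthetic-data
    generators with known ground truth make the whole workflow reproducible
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
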
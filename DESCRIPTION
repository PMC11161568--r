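Package: helicoidr
Title: Diagnostics for Photonic Helicoidal Cell Walls in Leaf Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to identify photonic helicoidal (Bouligand) cell walls in
    leaf epidermal cells from paired circularly polarized reflectance spectra
    and transmission electron micrographs. Implements the four-step
    diagnostic: circular-polarization-selective peak extraction, nested-arc
    scoring of oblique sections, lamellar half-pitch measurement from band
    images (including the groups-of-ten protocol), and the structure-colour
    concordance test lambda = n_m * p linking reflectance peak, mean
    refractive index and helicoid pitch. Ships a synthetic-data generator
    with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
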
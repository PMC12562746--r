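Package: tammsensor
Title: Transfer-Matrix Simulation of Tamm-Plasmon and Cavity-Mode
    Refractive-Index Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dispersive transfer-matrix simulator for one-dimensional layered
    photonic structures, specialised for asymmetric Tamm-plasmon/cavity
    refractive-index sensors. Builds metal-coated Bragg-mirror stacks with a
    central analyte cavity, computes reflectance, transmittance, absorptance,
    internal field profiles and angular/polarisation maps, locates and
    classifies resonance modes (Tamm plasmon polariton and cavity), and
    evaluates Q and G factors, reference-corrected sensitivity and figure of
    merit over analyte refractive-index sweeps, including a glucose-in-urine
    concentration map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
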
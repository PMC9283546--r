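Package: focisim
Title: Simulation of Radiation-Induced DNA Damage Foci Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates DNA double-strand-break (DSB) distributions in a
    flattened-ellipsoid nuclear geometry populated by TAD (topologically
    associating domain) beads, evolves the damage under a bi-exponential
    repair model, renders direct (Ku/DNA-PKcs) and indirect (gamma-H2AX)
    fluorescent-marker microscope images by point-spread-function
    convolution, counts foci with a scale-space Laplacian-of-Gaussian
    detector, and quantifies the miscount between detected foci and the
    ground-truth DSBs across radiation types, doses, time points and
    microscope configurations. Includes Standard DNA Damage (SDD) format
    input/output and a registry of published confocal/STED/multiphoton
    pixel spacings and numerical apertures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
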
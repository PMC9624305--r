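Package: neurotfm
Title: Traction Force and Atomic Force Microscopy Analysis of Neuronal Cell
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cell-substrate traction stress fields from
    fluorescent bead displacements by Fourier transform traction cytometry
    (FTTC) on an elastic half-space, measures substrate displacement fields
    by sub-pixel bead tracking, fits atomic force microscopy (AFM)
    force-indentation curves with the Hertz model for a conical tip to build
    cellular elasticity maps, and computes summary mechanics of neuronal
    cells: integrated traction forces over contact areas, stress time
    series, stiffness-traction coupling, and stiffness-actin overlap. A
    forward Boussinesq simulator generates fully synthetic scenes with known
    ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tiff,
    jsonlite,
    mgcv,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
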
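Package: monolayerTFM
Title: Traction Force and Monolayer Stress Microscopy for Cell Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cell-generated forces and intercellular stresses
    from substrate deformation experiments. Computes substrate deformation
    fields from bead-image pairs by drift correction and cross-correlation
    particle image velocimetry, inverts deformations to traction fields by
    Fourier Transform Traction Cytometry with a finite-substrate-thickness
    Green's tensor, recovers the two-dimensional stress tensor of a cell
    monolayer by a plane-stress finite element method with whole-system
    zero-translation and zero-rotation constraints, and reduces the fields
    to scalar measures (strain energy, contractility, average normal and
    shear stresses, stress heterogeneity, and cell-cell line tensions).
    Includes an analytic synthetic-data generator (square contractile patch
    with rendered bead images) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
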
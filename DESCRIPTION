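Package: thymometry
Title: Quantification of the Developing Thymic Epithelium from Sections,
    Stacks and Simulated Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify thymic epithelial cells (TECs) in the
    developing mouse thymus and to reconcile in-situ histology with flow
    cytometry after enzymatic dissociation. Includes a synthetic-data
    generator for two-reporter cryosection images and anisotropic
    light-sheet stacks with full ground truth, Laplacian-of-Gaussian
    nuclear spot detection in 2D and 3D, DAPI-density based cortex/medulla
    segmentation, compartment morphometry (TEC densities, cortical-to-
    medullary ratios, thymopoietic indices), stereological extrapolation
    of whole-organ TEC numbers with Abercrombie correction, and a
    dissociation/gating simulator with composition-weighted bulk
    expression for quantifying the preferential loss of cortical TECs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
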
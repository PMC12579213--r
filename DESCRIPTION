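Package: cellquant
Title: Quantification of Condensate-Based Interaction Screens and Cell
    Migration Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantitative fluorescence-microscopy readouts used
    in Rho GTPase signalling studies. Scores bait-prey protein-protein
    interactions from two-channel condensate images (formation efficiency,
    condensate signal-to-noise ratio, and their product, the protein
    interaction index), assembles and clusters GTPase-by-effector
    interaction matrices, computes cell-migration trajectory statistics
    (speed, directionality, turning angles, directional autocorrelation),
    implements a cell-boundary localization pipeline (segmentation,
    boundary normals, membrane regions, protrusive-wedge radial
    partitions, boundary windows, edge velocity, kymographs), detects
    actin stress-fiber orientations and focal-adhesion puncta, and fits
    one-phase association kinetics to fluorescence recovery curves. A
    synthetic-data module generates every input with recorded ground
    truth so the full pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
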
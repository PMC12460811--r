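Package: strain4d
Title: 4-D Myocardial Strain Mapping for Embryonic Zebrafish Hearts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs beating-heart dynamics from asynchronously
    acquired per-slice fluorescence movies and maps myocardial deformation
    over the cardiac cycle. Provides retrospective cardiac-phase
    synchronization of nongated microscopy, myocardial segmentation and
    surface meshing, cyclic deformable registration with a B-spline spatial
    model and a truncated temporal Fourier basis, per-element area strain
    with epicardial/endocardial regional summaries, and trabecular-ridge
    strain metrics (radial/circumferential shortening, transmural
    thickening, compact-layer circumferential strain). A synthetic
    beating-heart phantom with analytic ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
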
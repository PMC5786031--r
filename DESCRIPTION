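Package: coroxr
Title: Three-Dimensional Reconstruction and Structured Meshing of Coronary
    Arteries from Two X-Ray Angiography Views
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs three-dimensional coronary artery models from two
    uncalibrated X-ray angiography (XRA) projections. Implements a ray-casting
    model of C-arm image formation with detector misalignment terms,
    genetic-algorithm self-calibration of the eleven gantry parameters by
    reprojection error minimisation, temporal gating of frame sequences and
    spatial matching of centerline points by optimal subsequence bijection,
    B-spline centerline and NURBS lumen-surface reconstruction, and structured
    quadrilateral/hexahedral O-grid meshing of complete coronary trees with
    bifurcation trimming and per-element scaled-Jacobian quality reporting.
    Includes semi-automatic 2D centerline/border extraction (multiscale
    Hessian vesselness, fast marching, Dijkstra border search), a synthetic
    phantom generator with known ground truth, and signed surface-deviation
    and Hausdorff validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
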
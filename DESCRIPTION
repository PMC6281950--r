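Package: ecginverse
Title: Electrocardiographic Imaging Inverse Problem Solvers and
    Regularization Parameter Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing epicardial potentials from body-surface
    potential maps through a homogeneous torso volume-conductor model.
    Implements the method of fundamental solutions (MFS) and a finite-element
    (FEM) transfer matrix, zero-order Tikhonov and L1-norm current-density
    regularization (via a Dirichlet-to-Neumann operator and a generalized
    singular value decomposition), and five regularization-parameter choice
    criteria: GCV, robust GCV, CRESO, the U-curve and ADPC. Includes
    triangulated surface-mesh input/output and geodesic distances, evaluation
    metrics (relative error, correlation, pacing-site localization), and a
    synthetic heart-torso phantom generator with an analytic concentric-sphere
    forward oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
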
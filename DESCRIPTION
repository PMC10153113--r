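Package: topomesh
Title: Surface-Guided Mapping of 3D Cell Surfaces Between Cartesian,
    Spherical, Planar and Topographic Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bijectively maps closed 3D cell-surface triangle meshes (and
    associated per-vertex or volumetric signals) between five
    representations: the input Cartesian surface, a smooth genus-0
    reference surface obtained by conformalized mean curvature flow, the
    unit sphere, an equirectangular 2D (u,v) image, and a topographic
    (d,u,v) surface/volume built by normal propagation of the reference
    surface. Provides the associated conformal and area-distortion
    metrics, mesh-comparison statistics, and an unsupervised
    topography-guided instance segmentation pipeline for cell-surface
    protrusions (blebs, lamellipodia, filopodia), together with seeded
    synthetic-shape generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    mclust,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
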
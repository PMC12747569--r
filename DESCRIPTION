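Package: airforge
Title: Subject-Specific Airway Geometry Preparation for CFD and Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline that turns CT-like volumes of the upper
    respiratory tract into simulation-ready geometry and physics inputs:
    classical extrathoracic air-cavity segmentation (windowing, median
    denoising, sinogram-space metal-artifact reduction, Canny/Laplacian
    enhancement, marker watershed, isosurface extraction), repair of raw
    surface meshes to watertight CFD-grade triangulations (non-manifold
    removal, hole filling, vertex merging, volume-preserving Taubin
    smoothing, quality metrics), medial-axis centerline extraction via a
    radius-weighted Eikonal equation solved by fast marching, automated
    planar capping of inlets and outlets, turbulence and aerosol-particle
    boundary-condition calculators, and utilities that convert particle
    deposition records into radioactive point-source batches for Monte
    Carlo dose assessment. Ships a synthetic-fixture generator (CT
    phantoms, watertight bifurcating tube trees with known centerlines,
    mesh-defect injection) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
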
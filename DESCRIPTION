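Package: contourreg
Title: Contour-Constrained Global Surface Registration for Image-Guided Liver Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global (initialisation-free) rigid registration between a
    preoperative liver surface mesh and a partial, deformed, noisy
    intraoperative surface. Candidate feature correspondences from TOLDI
    (Triple Orthogonal Local Depth Image) descriptors are pruned by spectral
    matching on an affinity matrix that combines geodesic-distance consistency
    with a constraint anchored on the liver ridge-line contour; the rigid
    transform is then estimated by RANSAC with an RMSE and normal-angle
    acceptance test, optionally refined by iterative closest point. Includes
    mesh/point-cloud I/O (PLY, OBJ, STL, CSV), fast-marching geodesic
    distances, surface reconstruction for sparse targets, and a synthetic
    benchmark for robustness to partial views and deformation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
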
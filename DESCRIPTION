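Package: skullrec
Title: Skull Surface Reconstruction and Point-Cloud Completion Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for craniofacial skeletal reconstruction from
    triangle meshes segmented from CT: rigid landmark (frontozygomatic sutures +
    basion) alignment with ICP refinement, external-surface point-cloud extraction
    by multi-view depth rendering and back-projection with Poisson-disk
    simplification, virtual cuboid defect injection driven by scan quality scores,
    fixed-scale normalization, pluggable shape-completion backends (mirror
    baseline, stored predictions) with region-restricted merging, PCA normal
    estimation with consistent tangent-plane orientation and Poisson surface
    reconstruction, and region-restricted evaluation metrics (accuracy,
    completeness, Chamfer distance, Earth Mover's distance, F-score). Includes a
    synthetic two-shell skull fixture generator so the whole pipeline is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
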
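Package: cloudtruth
Title: Quality Evaluation of Vegetation Point-Cloud Reconstructions Against Reference Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative evaluation of photogrammetry-derived 3D
    vegetation point clouds against a known reference scene: target-based
    similarity-transform alignment with optional ICP refinement, exact
    nearest-neighbour distance fields with the standard distance-class
    colouring, octree-grid connected-component segmentation of floating and
    attached artefacts, and a voxel-based ROC/AUC reconstruction-quality
    statistic. Includes a procedural generator for labelled synthetic tree
    scenes (trunk, branches, foliage, grass ground, eight cube alignment
    targets) and a degrader that injects parameterized artefact classes
    (omission holes, floating clusters, attached rings, ghosts, jitter,
    thinning, pose perturbation), so the whole evaluation chain can be
    exercised end to end without photogrammetric software or imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
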
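Package: spineflow
Title: Dendritic Spine Segmentation Workflow for Confocal Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exercising a volumetric dendritic-spine
    segmentation workflow from confocal microscopy stacks. Includes
    voxelization of closed shaft and spine surface meshes into three-class
    label volumes, automatic reconnection of detached structures via A* path
    search and tolerance-based flood fill, class- and distance-weighted loss
    functions for training under weak annotations, a configurable 3D U-Net
    style encoder-decoder with patch-based training and tiled prediction,
    user-parameterizable postprocessing (noise removal, instance extraction,
    seeded watershed splitting, marching-cubes surface extraction), and a
    synthetic dendrite phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
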
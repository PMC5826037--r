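Package: miaclust
Title: Locally Adaptive Fuzzy C-Means Segmentation for Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Segmentation of three-dimensional micro-computed tomography
    (micro-CT) volumes of bone and fossil material by K-means-initialized
    global fuzzy c-means clustering followed by a locally adaptive
    refinement in overlapping cubes, with membership merging and an
    optional probability threshold. Includes sphere-fitting 3D local
    thickness measurement (Hildebrand-Ruegsegger definition) for
    validating segmentations, deterministic synthetic phantom generators
    (coiled plate, trabecular lattice, fossil-like volumes with intensity
    gradients, bright inclusions and noise), parameter-sweep utilities,
    NIfTI-1 and multi-page TIFF input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    tibble,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
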
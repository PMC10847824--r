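Package: octvbm
Title: Voxel-Based Morphometry for Macular OCT Layer-Thickness Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatial normalization of macular optical coherence tomography
    (OCT) layer-thickness maps to a common target space (fovea-anchored 2D
    translation plus per-A-line 1D affine depth alignment), followed by
    voxel-wise statistical mapping: general linear models with covariates,
    Benjamini-Hochberg false discovery rate control with cluster-extent
    filtering, percentage-change maps, voxel-wise covariate regression, and
    voxel-wise test-retest reliability mapping (within-subject SD,
    coefficient of variation, intraclass correlation). Includes a synthetic
    retinal phantom generator with known ground truth for validation, and a
    command-line pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    RNifti,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
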
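Package: threshsurf
Title: Threshold Sensitivity of Bone Surface Models Segmented from CT and
    CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the choice of a single grey-intensity
    threshold affects bone surface models segmented from 3D radiographic
    volumes (CT and cone-beam CT). Implements interface-voxel
    reference-threshold estimation, isosurface extraction at a family of
    thresholds, point-to-plane iterative closest point superimposition,
    mesh-to-mesh mean absolute distance, and permutation-based
    multivariate statistics, together with a synthetic two-material
    phantom generator (partial-volume blur, noise, multiplicative bias
    field) that provides analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
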
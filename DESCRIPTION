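Package: wmhseg
Title: Single-Channel FLAIR White Matter Hyperintensity Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automatic segmentation of white matter hyperintensities
    (WMH) on bias-corrected, skull-stripped 3T FLAIR volumes. The pipeline
    applies edge-preserving anisotropic diffusion, removes unambiguously
    hyperintense voxels on a z-score criterion, clusters each slice with
    two-class fuzzy C-means in the axial and coronal planes, thresholds
    background-CSF membership grades, locates a dual-histogram break point
    to segment hyperintensities per slice, and intersects the two planes.
    Optional false-positive minimization masks candidates with a registered
    white matter probability template, either directly or via a 3D
    connectivity rule. Includes Dice-type similarity metrics, a FLAIR-like
    phantom generator, and a synthetic-lesion precision experiment with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
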
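Package: lhmorph
Title: Whole Left-Heart Morphometrics from 4D Endocardial Landmark Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical shape analysis of beating left-heart (left ventricle
    plus left atrium) endocardial landmark clouds. Provides generalized
    Procrustes superimposition in shape and size-and-shape space,
    interpolation of cardiac cycles at electro-mechanically homologous times,
    linear-shift parallel transport of within-cycle deformations to a common
    template, motion-trajectory attributes (shape, centroid size, orientation
    angles) with permutation ANOVA/MANOVA, two-block partial least squares
    covariation between the two chambers with permutation effect sizes and
    major-axis slopes, thin-plate-spline bending-energy (partial-warp)
    disintegration slopes, randomized-split support-vector-machine
    classification, and a synthetic 4D left-heart generator for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
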
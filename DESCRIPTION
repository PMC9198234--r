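Package: femurfe
Title: Segmentation Sensitivity Analysis for Finite Element Models of the
    Femoral Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how small, controlled variations in CT bone
    segmentation propagate into finite element (FE) biomechanics. Provides a
    synthetic femoral-head phantom generator with ground-truth bone masks,
    Kittler-Illingworth minimum-error thresholding together with narrowed
    intermediate-percentage variants (KI-99.0, KI-97.5, KI-95.0), voxel-based
    surface and tetrahedral meshing with standardization (cropping at the
    head-neck junction and Z-axis orientation), a small-strain isotropic
    linear-elastic tetrahedral FE solver for a standardized compressive load
    case, and group statistics comparing mean displacement, hydrostatic
    pressure, von Mises stress and effective Lagrange strain across
    segmentation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
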
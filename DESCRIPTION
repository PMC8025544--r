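Package: sctval
Title: Validation Toolkit for Synthetic CT in MRI-Only Brain Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end validation of synthetic CT (sCT) images against
    reference CT for MRI-only brain radiotherapy planning. Provides
    Hounsfield-unit accuracy metrics (MAE, ME, bone Dice overlap) with a
    post-surgical volume-of-interest sub-analysis, B0-map geometric
    distortion quantification and marker-phantom system-distortion
    analysis, DVH endpoint extraction and 3D global gamma comparison of
    dose distributions with a dose cut-off, 6-DoF rigid bone-window
    registration with registration-delta analysis and treatment-couch
    localisation in low-SNR ZTE-like images, plus a seeded digital
    head-phantom cohort generator (skull with optional bone-resection
    defects, class-conditional sCT perturbations, B0 fields, analytic
    dose grids, marker phantoms) so the full pipeline can be exercised
    and verified without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    jsonlite,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
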
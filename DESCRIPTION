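Package: mvctreg
Title: Elastic kVCT-MVCT Registration and Lung Correspondence Analysis for
    Helical Tomotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deformable registration of daily megavoltage CT (MVCT) images to
    the planning kilovoltage CT (kVCT) for helical tomotherapy of lung cancer.
    The spatial model is a global rigid transformation plus a cubic B-spline
    free-form deformation, estimated by minimising negative Mattes-form mutual
    information under a four-level multi-resolution schedule with an L-BFGS-B
    optimiser.  The package also provides the full accuracy-assessment suite
    used to validate such registrations (border-trimmed correlation
    coefficient, landmark target registration error, region-growing lung
    segmentation, lung volume/centroid/Jaccard correspondence, cohort
    aggregation with Wilcoxon signed-rank comparisons) and a synthetic thorax
    phantom generator with ground-truth deformations for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
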
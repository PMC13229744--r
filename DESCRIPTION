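Package: rtdgc
Title: Dose Gradient Curve and DVH Analysis for Radiotherapy Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of dose fall-off in radiotherapy treatment
    plans from DICOM RT Dose, RT Structure Set and (optionally) RT Plan files.
    Computes differential and cumulative dose gradient indices (dDGI, cDGI)
    from concentric isodose shells, voxel-based cumulative dose-volume
    histograms with the standard clinical metrics (Dx, Vx, mean/max/min),
    conformity and gradient indices (Paddick CI, GI, R50), and a four-tier
    clinical quality grading of the dose gradient at the prescription
    isodose. Includes a synthetic spherical-phantom generator with
    closed-form isodose geometry for validation, batch cohort analysis
    with correlation and subgroup statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
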
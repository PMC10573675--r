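Package: stonevol
Title: Kidney Stone Volumetry and Observer Agreement from Density-Window CT Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures renal stone burden on non-contrast CT by Hounsfield-window
    threshold segmentation: voxels inside an operator-chosen density window are
    labeled into connected components and each stone's volume (voxel count times
    voxel volume), maximum diameter and attenuation statistics are reported.
    Includes the classical geometric volume estimators (sphere, ellipsoid,
    Ackerman, cumulative diameter, surface area) for comparison, a pluggable
    lithotripsy-duration model (volume divided by a calibrated ablation rate),
    a full inter-/intra-observer agreement suite (Lin concordance correlation
    with confidence intervals, Kendall's coefficient of concordance with tie
    correction, coefficients of variation, Bland-Altman limits of agreement and
    repeatability coefficient, Mann-Whitney subgroup tests), and a synthetic CT
    phantom simulator with analytic ground truth and an observer model for
    end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
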
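Package: fetquant
Title: Quantitative Agreement Analysis of PET Attenuation-Correction
    Methods for Amino-Acid Brain Tumor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating MR-derived attenuation-correction (AC)
    methods against a CT reference in FET-PET brain tumor imaging.
    Provides a seedable synthetic phantom generator whose multiplicative
    bias fields emulate the spatial error structure of MR-based AC
    (global underestimation, radial surface-to-center gradients, focal
    nodular warps and metal-implant signal voids); isocontour tumor
    delineation at an adaptive background-relative threshold; the
    clinical metrics T_MEAN/B, T_MAX/B and biological tumor volume
    (BTV); spatial agreement measures (Jaccard index, peak-location
    shift, smoothed-difference shape-deviation analysis); log-scale
    Bland-Altman limits of agreement with a one-way variance-components
    correction for repeated measurements; clinically motivated
    acceptance-criteria classification; and longitudinal follow-up
    change analysis across mixed AC pairings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
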
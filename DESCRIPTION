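Package: ddacc
Title: Deformable Dose Accumulation for Adaptive Prostate Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing online-adaptive MR-guided radiotherapy,
    simulated conventional image-guided radiotherapy, and the static
    reference plan of a prostate treatment course by deformable dose
    accumulation. Provides spatial volume/mask/vector-field containers with
    NIfTI-1 input and output, trilinear and nearest-neighbour grid
    resampling, translation-only rigid registration, a structure-guided
    multi-resolution demons deformable registration, direct dose mapping
    along displacement fields, dose-volume histogram and dose-volume
    parameter extraction, planning-objective checking, EQD2/gEUD/LKB NTCP
    radiobiology, paired nonparametric statistics, and a seeded synthetic
    pelvis cohort generator with ground-truth deformations for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
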
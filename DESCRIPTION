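Package: lipioquant
Title: Automated Quantification of Lipiodol Deposition on Post-Chemoembolization CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, threshold-based volumetric quantification of
    Lipiodol deposition on 24-hour post-cTACE non-contrast CT. Derives
    Hounsfield-unit density cut-offs per tumor by bilevel histogram
    thresholding (between-class variance and minimum cross-entropy), pools
    them into cohort-level low/mid/high density thresholds, classifies
    per-lesion deposition patterns (homogeneous, sparse, rim, peripheral)
    by morphology in physical units, quantifies enhancing tumor volume
    response on baseline and follow-up MRI with the qEASL rule, registers
    MRI tumor masks to CT with a mask-driven diffeomorphic demons
    deformation, and generates seeded synthetic lesion phantoms with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
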
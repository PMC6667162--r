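Package: densicalib
Title: Phantom and Phantomless HU-to-BMD Calibration for Quantitative CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration of Hounsfield units (HU) to calcium-hydroxyapatite
    equivalent bone mineral density (BMD) for quantitative CT of the femur.
    Implements the gold-standard four-rod calibration-phantom fit, an
    automated phantomless "air-fat-muscle" calibration that locates tissue
    peaks in an HU histogram of the patient's leg, a non-patient-specific
    cohort-average calibration, and cross-scanner/kernel HU harmonisation.
    Ships a synthetic leg-on-phantom CT generator with known ground truth so
    every calibration stage can be verified by round-trip parameter
    recovery, plus Bland-Altman method-agreement statistics and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
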
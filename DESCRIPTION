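Package: metstabr
Title: LC-MS/MS Bioanalytical Validation and Microsomal Metabolic Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative bioanalysis toolkit for LC-MS/MS assays in drug
    metabolism work: weighted linear calibration with back-calculation and
    LOD/LOQ, the FDA-style validation statistic suite (precision, accuracy,
    recovery, matrix effect, IS-normalized matrix effect, carryover,
    stability), and the substrate-depletion workflow that converts human
    liver microsome incubation time courses into in vitro half-life,
    intrinsic clearance, and a clearance class. A synthetic-data module
    simulates calibration sets, QC tables, matrix-effect sample pairs,
    depletion time courses, and MRM chromatograms with known ground truth,
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
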
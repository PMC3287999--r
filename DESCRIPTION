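Package: adiposcreen
Title: Arrayed RNAi Screen Analysis for Adipocyte Lipid Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for arrayed siRNA screens of lipid
    accumulation in primary human (pre)adipocytes. Implements cell-number
    correction of lipid readouts from a DNA-signal calibration slope,
    per-plate normalized percent inhibition (NPI) and screen-wide Z-score
    normalization with Z'-factor quality control, 2-of-3 threshold hit
    calling together with rank-based redundant siRNA activity (RSA)
    p-values, secondary-screen validation, In-Cell Western two-marker
    differentiation versus lipid-turnover phenotype classification,
    microarray fold-change/p-value regulation filtering, and 2^-ddCt
    relative quantification. Includes a synthetic screen generator with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
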
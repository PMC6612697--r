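Package: igdose
Title: Gamma Index and Inverse Gamma Analysis for Planar Dose
    Distributions
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Compare planar radiotherapy dose distributions for
    patient-specific quality assurance. Implements the global gamma index
    and gamma agreement index (GAI) with a lower dose threshold, and the
    inverse gamma method: iterative searches that report the minimum
    distance-to-agreement criterion, minimum dose-difference criterion, or
    ratio-linked criteria pair needed to reach a target pass rate,
    together with per-point requirement maps and histograms. Includes a
    synthetic dose-field generator with analytic shifts for validation, a
    plain-text dose-grid format, optional DICOM RT Dose ingestion, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
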
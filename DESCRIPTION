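Package: cardiomotion
Title: Contractility Quantification of Beating Cardiomyocyte Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Video-based quantification of cardiomyocyte monolayer
    contractility. Estimates per-frame displacement fields relative to a
    diastolic reference frame by windowed normalized cross-correlation
    (particle image velocimetry), converts them to a nondimensional
    contractility trace via the divergence of the displacement field, and
    segments beats to report chronotropic and inotropic parameters (beat
    period, contraction duration, peak and mean contractility). Includes a
    synthetic speckle-video generator with analytically known displacement
    and divergence for validation, and the relative-quantification
    arithmetic used alongside such assays (2^-ddCt fold changes, percent
    differences, unpaired t tests).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
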
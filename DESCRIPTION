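Package: fibersect
Title: Cross-Section Morphometry of Cotton Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for phenotyping cotton fibers from resin-embedded
    cross-section micrographs. Detects individual fiber cross-sections
    (outer wall plus lumen) with classical image operators, converts pixel
    measurements to micrometres via a reference-distance calibration, and
    derives the standard maturity metrics: degree of cell-wall thickening
    (theta), fiber fineness in millitex, maturity ratio, and standard
    fineness. Includes rule-based quality filtering with a pluggable scorer,
    import of manual measurement logs, per-line summaries with one-way
    ANOVA, pairwise t tests, Tukey-Kramer HSD and compact letter displays,
    and a synthetic micrograph generator with exact ground truth so the
    whole pipeline is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stringr,
    EBImage,
    mgcv,
    png,
    tiff,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
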
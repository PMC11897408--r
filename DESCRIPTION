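Package: decondenseR
Title: Quantification of Mitotic Chromatin Decondensation from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for measuring mitotic chromatin
    decondensation. Implements the border-smoothness score for in-vitro
    chromatin substrates (intersection-over-union of a segmented chromatin
    mask against a median-filter-softened version of itself), Otsu-based
    segmentation recipes for fixed and live-cell imaging, anaphase-aligned
    normalized chromatin-area time courses, mitotic phase classification and
    dwell times, perichromatin marker intensity and cytoplasmic foci
    quantification, and a normality-gated two-sample statistics layer.
    Ships a synthetic fluorescence-microscopy generator with ground truth so
    every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
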
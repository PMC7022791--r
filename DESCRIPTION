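Package: hamfrac
Title: Multifractal Image Analysis of Fat Marbling in Tissue Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for phenotyping fat infiltration (marbling) in digital
    photographs of tissue slices, in particular dry-cured ham. Implements a
    reproducible image pipeline (square crop, Rec. 601 grayscale, Gaussian
    high-pass illumination correction with Overlay blending, dual-threshold
    binarization into fat/muscle masks, and coordinate-table export) together
    with a sandbox estimator of the generalized Renyi dimensions D0
    (capacity), D1 (information) and D2 (correlation) of the segmented fat
    phase. A synthetic slice generator produces marbled images with known
    ground-truth masks and controllable multiplicative illumination
    heterogeneity, plus benchmark fractals (Sierpinski carpet, filled square,
    line) with analytic dimensions, so the whole pipeline can be validated
    without any reference photographs. Batch orchestration, per-class summary
    statistics and dispersion comparisons across filtering methods are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    jpeg,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
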
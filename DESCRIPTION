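Package: reefwarp
Title: Top-Down Transformation of Oblique Reefscape Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes perspective distortion from oblique underwater reefscape
    photographs by detecting each scene's perspective geometry (horizon line,
    camera roll, transformable reef plane, vanishing geometry) and
    brute-force searching the inverse-perspective-mapping homography until
    the drawn perspective grid measures ninety degrees, yielding a top-down
    view suitable for quantitative analysis of reef condition. Includes
    checkerboard camera calibration with a Brown distortion model, a seeded
    synthetic-scene generator with analytic ground truth, and a batch
    processing interface with a typed failure taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    parallel,
    png,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
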
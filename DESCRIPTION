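Package: wheatdens
Title: Wheat Plant Density Estimation from High-Resolution RGB Field Imagery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates wheat plant density (plants per square metre) at early
    growth stages (around Haun stage 1.5) from high-resolution RGB images of
    seedling rows. The pipeline segments green vegetation with Otsu
    thresholding on the CIELab a* channel, rectifies the perspective view to a
    metric orthoimage using a chessboard-calibrated homography, detects crop
    rows with an edge-point Hough transform, extracts thirteen morphological
    features per connected component (region, moment-ellipse and skeleton
    features), estimates the number of plants per component with a
    one-hidden-layer tangent-sigmoid network pruned by weight-based recursive
    feature elimination, and aggregates the continuous per-object counts to a
    density over the imaged row segments. A ground-truthed synthetic scene
    generator emulating rows of overlapping green seedlings on textured soil
    supports training and validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
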
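Package: depotmri
Title: Quantitative MRI Morphometry of Large-Volume Subcutaneous Injection Depots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying large-volume subcutaneous (LVSC) saline
    depots from stacks of axial T2-weighted MRI slices: a synthetic imaging
    phantom with exact ground truth emulating an incremental injection series
    (naive, cannula insertion, 2/5/10 mL, post-removal), histogram-based depot
    segmentation, extraction of the intradermal/subcutaneous and
    subcutaneous/intramuscular boundary surfaces, correction of the four
    characteristic artifacts (invisible dermis gap, metal-cannula void,
    grayscale attenuation, breathing stair-step), least-squares rigid series
    alignment, and depot/tissue morphometrics (depot volume, depth, projected
    area and principal axes, subcutaneous thickness maps and reference-point
    thickness tracking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
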
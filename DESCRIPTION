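Package: pointseg
Title: Weakly Supervised Nucleus Segmentation from Point Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage weakly supervised segmentation of cell nuclei in
    histology images using only one point annotation per nucleus. Point
    annotations are expanded into complementary pseudo-labels (tri-state
    Voronoi labels and binary SLIC superpixel labels); a three-branch
    convolutional model (segmentation, attention and constraint networks)
    is trained jointly on the pseudo-labels, and a confident-learning pass
    then corrects the superpixel labels pixel-wise before retraining.
    Includes a synthetic histology generator with exact ground truth, a
    pure-R reverse-mode network engine, evaluation metrics and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
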
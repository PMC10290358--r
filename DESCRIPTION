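Package: reedcover
Title: Patch-Based Convolutional Mapping of Common Reed Cover in Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects common-reed (Phragmites australis) cover in RGB aerial or
    drone imagery with a compact convolutional neural network trained on
    overlapping square crops of pure-class photographs. Provides fifty-percent
    overlap tiling, a shuffled 70/30 train/validation split, a two-convolution
    two-pooling softmax classifier written in base R, confusion-matrix
    evaluation, per-pixel coverage maps with a scalar coverage fraction, a
    procedural generator of synthetic reed/water scenes with exact ground-truth
    masks, and packaged reed-chemistry reference tables with a conductometric
    cell-constant calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
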
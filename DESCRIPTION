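Package: microres
Title: Micro-Expression Recognition with Pixel Residual Sums and
    Overlapping Pyramid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for facial micro-expression recognition from short
    annotated video clips. Collapses the onset-to-apex window of a clip into a
    single residual-sum image (absolute or min-max rescaled), crops faces from
    68-point landmarks, tiles each image with a two-level Gaussian pyramid of
    overlapping crops, extracts per-tile features with a small
    increasing-channel depthwise convolutional network, fuses them with
    trainable position embeddings, and evaluates with leave-one-subject-out
    UF1/UAR/accuracy in the MEGC2019 style. Ships a synthetic clip generator so
    the full pipeline is testable without access-restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
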
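Package: camlink
Title: Linking CNN Saliency Maps to Breast Lesion Characteristics in Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining convolutional neural network classification
    decisions on breast-ultrasound lesion images in terms of domain-known
    cancer characteristics. Implements entropy-gated gradient class-activation
    maps (EGrad-CAM) and ablation-based class-activation maps (Ablation-CAM),
    region masks for calcification, echogenicity, shape and margin signs,
    outcome-stratified contribution statistics with categorical grading, and
    confidence-based heatmap-faithfulness metrics (average drop, percent
    increase in confidence, win percentage). Ships a seeded synthetic
    ultrasound-like lesion generator with full ground-truth annotations and a
    small trainable from-scratch CNN backend so the whole framework runs end
    to end without external data or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
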
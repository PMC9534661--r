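Package: daunet
Title: Attention-Gated Coarse-to-Fine U-Net Segmentation of CT Angiography
    with Perforator Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of contrast-enhanced arteries in computed tomography
    angiography (CTA) volumes with a deeply supervised, attention-enabled U-Net
    (DA-UNet): squeeze-and-excitation channel weighting, additive attention
    gates on the encoder skip connections, multi-scale deep supervision, and a
    two-stage coarse-to-fine cascade that localizes the artery at reduced
    resolution before fine segmentation inside its bounding box. Includes
    multi-view candidate fusion, the five voxel-count segmentation metrics
    (Dice, Jaccard, sensitivity, balanced-accuracy AUC, relative volume
    difference) plus an average Hausdorff surface distance, a seeded synthetic
    CTA vessel-phantom generator with ground-truth perforator exit points, and
    the perforator-localization geometry (landmark coordinate frame, skin
    surface projection, point-set matching with detection concordance
    statistics). The network engine is implemented in base R on top of BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    tibble,
    generics,
    ggplot2,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
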
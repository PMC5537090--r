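Package: autobaa
Title: Fully Automated Bone Age Assessment from Hand Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for automated skeletal bone age assessment
    (BAA) from pediatric hand/wrist radiographs: grayscale-base and size
    normalization, a patch-classification convolutional network that labels
    every pixel as bone, tissue, background, collimation or annotation
    marker, largest-component hand mask generation, a vision pipeline
    (masking, centering, in-mask histogram equalization, denoising,
    sharpening), an exactly enumerated affine and photometric augmentation
    engine, a transfer-learning classification harness with layer-wise
    fine-tuning over the 14 one-year age classes (5-18 years), occlusion
    sensitivity attention maps, evaluation metrics (within-k-year accuracy,
    RMSE, mAP, mIoU), and structured report generation. Ships a synthetic
    phantom radiograph generator with per-pixel ground truth and an
    age-dependent growth-plate gap so every stage is testable end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
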
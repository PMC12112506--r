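Package: wsiseg
Title: Cascaded Patch-Wise Classification and U-Net Refinement for
    Whole-Slide Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-slide-image (WSI) tumor segmentation with a
    two-stage cascade: a patch-wise classifier built by fusing truncated
    convolutional backbones scores 224x224 tiles, the per-tile tumor
    probabilities are stitched into a heatmap, and a lightweight U-Net
    refines the heatmap jointly with a down-sampled RGB view of the slide.
    Includes the multi-lens distortion augmentation (randomly placed local
    barrel/pincushion warps with nearest-neighbour gathering), tissue
    detection and tile labelling rules for hematoxylin-eosin slides,
    segmentation metrics (Dice, IoU, average Hausdorff distance),
    model-complexity profiling (exact parameter counts and FLOP estimates
    for standard backbones), gradient saliency maps, and a synthetic
    H&E-like fixture generator so the full cascade is testable without
    clinical cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    grDevices,
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Classification, Segmentation
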
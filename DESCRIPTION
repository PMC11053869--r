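Package: dhcnn
Title: Dilated Heterogeneous Convolutions for Cell Detection and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the dilation heterogeneous convolution (DHConv) operator,
    in which a fraction P of the kernels in each convolution filter are dilated
    K-by-K kernels and the remainder are 1-by-1 pointwise kernels, together with
    the analytic FLOPs and receptive-field cost model for such layers, conversion
    of ResNet-style backbones to DHConv, a compact trainable cell
    detection/segmentation network built from DHConv layers, an instance
    segmentation evaluation suite (precision, recall, Dice, average precision and
    panoptic quality), COCO-style annotation input/output with polygon/mask
    conversion, and a seeded synthetic microscopy scene generator for fully
    offline training and evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
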
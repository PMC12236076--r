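Package: phrfdetr
Title: Lightweight Real-Time Detection Transformers for Weed Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the PHRF-RTDETR family of lightweight real-time
    detection transformers for weed detection in upland rice: the PGRNet
    backbone built from partial/group-convolution residual blocks
    (PGRBlock), the AIFI-HiLo intra-scale encoder with high/low-frequency
    attention, the RetC3 fusion block with spatially decayed decomposed
    attention (MaSA), and the Focaler-WIoUv3 bounding-box regression loss.
    Provides exact parameter and FLOP accounting for all ablation
    variants, NMS-free prediction, detection metrics (precision, recall,
    AP, mAP, F1, confusion matrices), YOLO-text and VOC-XML annotation
    interchange, the split-before-augmentation dataset protocol, and a
    seeded procedural generator of five-class weed scenes so the whole
    stack is buildable and testable without external data. Network layers
    run on a compact array-based neural core with reverse-mode automatic
    differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
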
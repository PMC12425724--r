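Package: braindet
Title: Attention-Augmented Single-Stage Detection for Brain Tumor MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for a lightweight single-stage brain tumor
    detector on MRI slices. Provides three attention operators for
    convolutional feature maps (a parameter-free shuffle-and-inhibit gate,
    a pooled-descriptor spatial gate, and a dual-branch channel attention
    block), the hook-reweighted HKCIoU bounding-box regression loss along
    with the IoU/CIoU family and distribution focal loss, a declarative
    model-graph builder for the YOLOv11n baseline and its attention-modified
    variant with exact parameter and FLOP accounting, a synthetic brain-scene
    generator emitting YOLO-format annotations, and a CPU micro
    training/evaluation harness with COCO-style mean average precision.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
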
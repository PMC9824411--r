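Package: pestvision
Title: Plant Pest and Disease Detection with Inception-Augmented YOLO,
    Clustered-Anchor RCNN and Model Ensembling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting plant pests and foliar diseases in RGB
    images: an Inception-augmented one-stage detector in the YOLOv3
    family, a two-stage region-proposal detector whose anchor boxes are
    designed by K-means clustering under an IoU distance, a weighted-box
    ensemble of the two, transfer-learning classifier heads for foliar
    disease images, photometric and geometric data augmentation with
    bounding-box bookkeeping, VOC-style precision/recall/AP/mAP
    evaluation, and a seeded synthetic pest-scene generator so the whole
    stack is testable without photographic data. Annotations are read
    and written in VOC XML, COCO JSON and YOLO text dialects. All
    tabular results are tibbles and compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
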
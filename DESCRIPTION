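Package: nodulescan
Title: High-Throughput Soybean Root-Nodule Phenotyping from Bounding-Box
    Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic toolkit for bounding-box phenomics of soybean
    root nodules on full-resolution 2D root images. Decomposes large images
    into overlapping 512x512 patches, remaps rectangle annotations between
    image and patch coordinate frames, stitches per-patch detections back
    into the full image with edge filtering and non-maximum suppression,
    extracts 24 nodulation traits from the final bounding boxes, scores
    detections against ground truth (confusion counts, precision, recall,
    F1, nodule-count-bin reports), and prepares GWAS-ready phenotype tables
    (Z-score outlier removal, trait summaries, Pearson correlations).
    Includes a synthetic root-scene generator and a configurable mock
    detector so every stage is testable without a trained model, plus a
    classical blob detector and an adapter slot for an external detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
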
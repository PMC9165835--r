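Package: CowPose
Title: Bottom-Up Multi-Animal Pose Estimation and Pose Classification for Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for bottom-up 2D pose estimation of dairy cows in
    surveillance imagery: a 16-keypoint skeleton model with visibility
    semantics, Gaussian keypoint heatmap and part affinity field (PAF)
    encoding and decoding, PAF line-integral limb scoring with Hungarian
    bipartite matching and greedy skeleton assembly, YOLO-style bounding-box
    geometry with complete-IoU (CIoU) loss and non-maximum suppression, a
    fully connected skeleton-coordinate classifier for standing/walking/lying
    poses, object keypoint similarity (OKS) evaluation, and a synthetic
    stick-cow scene generator so that every pipeline stage is testable
    without farm footage. Readers and writers are provided for Labelme
    keypoint JSON, PascalVOC XML boxes and COCO-keypoints JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml,
    clue,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
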
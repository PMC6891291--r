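Package: bovimetrics
Title: Non-Contact Livestock Body-Dimension Measurement from 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for measuring the body dimensions of standing
    quadruped livestock (withers height, chest depth, back height, waist
    height, body length) from LiDAR-style 3D point clouds. Covers ASCII
    PCD/PLY/XYZ input and output, a synthetic scene generator with known
    ground truth, a filtering fusion (conditional range filter, statistical
    outlier removal, voxel downsampling), subject isolation by RANSAC ground
    removal and Euclidean clustering, rigid data augmentation, a Kd-tree
    deep network point-cloud classifier with TrAdaBoost instance-transfer
    retraining, PCA pose normalization with orientation correction,
    principal/mean/Gaussian curvature surface typing, FPFH landmark
    recognition against a feature-model database, and an automatic-versus-
    manual error report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
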
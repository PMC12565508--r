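Package: fruitvol
Title: Non-Destructive Fruit Volume Estimation from Calibrated Two-View Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the volume of roughly ellipsoidal fruit (oranges and
    similar produce) from paired top and side silhouette images calibrated
    with a fiducial marker of known physical size. Converts pixel
    measurements to millimetres, derives a 25-element physics-aware feature
    set (ellipsoid volume proxies, Ramanujan ellipse perimeters,
    Knud-Thomsen surface areas, sphericity, eccentricities, cross-view
    ratios and interaction terms), and maps features to volume with a
    leakage-free, monotonicity-constrained two-layer stacked
    gradient-boosting ensemble combined by a Lasso meta-learner. Includes a
    superellipsoid-based synthetic fruit generator with an exact volume
    oracle, quantile-stratified cross-validation, IQR outlier capping,
    log-scale target modelling, Table-style multi-model comparison with
    paired Wilcoxon testing, and object-detection evaluation utilities
    (IoU, precision, recall, mAP@50).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
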
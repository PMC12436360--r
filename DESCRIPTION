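Package: OrbitCSL
Title: Cross-Sequence Learning for Orbital Fracture Detection on Radiograph Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements cross-sequence learning for multi-input image
    classification: each original radiograph is paired, without replacement,
    with a same-label region-of-interest (ROI) crop chosen by lowest raw-pixel
    cosine similarity, and the pair is classified by two parallel vision
    transformer encoders fused by feature concatenation. Includes a synthetic
    orbital-radiograph phantom generator with ground-truth fracture labels and
    ROI boxes, stratified split and cross-validation drivers, a complete
    diagnostic-accuracy evaluation stack (AUROC, Youden cutoff, confusion
    metrics with exact binomial confidence intervals, DeLong and McNemar
    tests, two-session reader-study tables), and gradient-weighted class
    activation mapping with bounding-box localization for positive
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
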
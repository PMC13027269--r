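Package: pestfusion
Title: Multi-Scale Vision-Sensor Collaborative Recognition of Small-Target Crop Pests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for image-level recognition of small-target crop pests
    (aphids, thrips, whiteflies and similar arthropods that occupy a tiny
    fraction of image pixels) from paired visual and environmental-sensor
    data. Provides a synthetic multimodal data generator emulating field
    acquisitions (cluttered leaf backgrounds, class-conditional microclimate
    streams, sensor outliers, missing records and clock mismatch), a
    preprocessing pipeline (bilinear resolution normalization, crop-based
    small-target enhancement, random scale perturbation, sigma-rule outlier
    removal, linear gap interpolation, nearest-timestamp image-sensor
    alignment, z-scoring), a multi-scale convolutional classifier with
    channel attention, learnable cross-scale fusion, environment-conditioned
    channel modulation and a vision-sensor collaborative head, and a
    group-aware training and evaluation harness (grouped 70/15/15 split,
    grouped 5-fold cross-validation, per-class / macro / support-weighted
    metrics, density-stratified evaluation, ablation grid). The network and
    its reverse-mode differentiation are implemented on plain BLAS matrix
    operations, so the package has no deep-learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
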
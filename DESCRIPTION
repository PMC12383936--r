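Package: lusaug
Title: Semantics-Preserving Data Augmentation for Lung Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Field-of-view aware preprocessing and stochastic data augmentation
    for B-mode lung ultrasound images, designed for positive-pair generation in
    joint-embedding self-supervised learning. Provides the semantics-preserving
    preprocessing workflow (binary FOV masking and tight cropping), a standard
    photographic augmentation pipeline, an ultrasound-specific pipeline built on
    scan-conversion geometry (probe-type and convexity changes, depth simulation,
    speckle/Gaussian/salt-and-pepper noise, wavelet-shrinkage denoising, CLAHE),
    and a distilled four-transform pipeline. Includes a synthetic lung ultrasound
    phantom generator with ground-truth masks and labels, and a leave-one-out
    ablation harness with grouped cross-validation, AUROC scoring, Friedman and
    Wilcoxon signed-rank tests under Holm-Bonferroni familywise control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
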
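Package: salvox
Title: Validating Attribution Saliency Methods for Volumetric Brain-Age CNNs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained framework for validating attribution-based saliency
    methods applied to 3D convolutional brain-age regressors. Generates synthetic
    age-encoded brain phantoms with labeled tissue classes, injects a surrogate
    ground truth by dilating the lateral ventricles into adjacent white matter in
    proportion to chronological age, trains a configurable 3D CNN brain-age model,
    computes seven gradient-based attribution maps (gradient saliency, input x
    gradient, masked gradient, guided backpropagation, guided Grad-CAM, integrated
    gradients, gradient SHAP), and scores each map against the ground truth with
    five similarity metrics (Dice, normalized mutual information, normalized
    scan-path saliency, Pearson correlation, histogram intersection similarity),
    reporting percent differences against a masked-gradient baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
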
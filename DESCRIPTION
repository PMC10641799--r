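Package: octlan
Title: Lesion-Aware Attention Networks for Volumetric Retinal OCT Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of volumetric retinal optical coherence tomography
    (OCT) scans with a lesion-aware attention network. Provides a B-scan
    preprocessing chain (macular slice selection, center crop, binarization,
    morphological dilation, largest-contour foreground extraction, volume
    assembly), a 3D residual convolutional network with named feature taps,
    gradient-weighted class activation mapping (Grad-CAM) with binarization
    into lesion masks, a mask-guided self-attention module inserted into the
    backbone, a two-stage training procedure (baseline first, attention network
    guided by the baseline's activation masks second), patient-level k-fold
    cross-validation with accuracy/sensitivity/specificity/ROC reporting, and a
    synthetic OCT phantom generator so the whole pipeline is testable without
    clinical data. The network engine (3D convolution, normalization, pooling,
    attention, Adam) is implemented in vectorized base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
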
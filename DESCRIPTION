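Package: farnet
Title: Feature-Wise Attention-Based Relation Networks for Multilabel Defect Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilabel surface-defect image classification with a feature-wise
    attention-based relation network (FAR-Net). A convolutional backbone is
    augmented with label-wise feature aggregation (one spatially softmax-normalised
    channel per label), squeeze-and-excitation channel gating, and scaled
    dot-product attention across labels that models semantic co-occurrence between
    defects (for example, rot accompanying cracking on dried jujubes). Includes a
    census-exact synthetic jujube-defect image generator, a staged SGD training
    protocol with module freezing, multilabel evaluation metrics (per-label average
    precision, mAP, micro/macro-F1, confidence grids), ablation switches for each
    module, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: png, jsonlite, yaml, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
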
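Package: swinleaf
Title: Two-Channel Shifted-Window Vision Transformer for Leaf Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies ligneous plant leaf diseases with a two-channel
    hierarchical vision transformer. The upper channel consumes the raw RGB
    image; the lower channel consumes an edge image produced by a trainable
    Sobel layer (gradient-magnitude map, initialized to the classical Sobel
    pair and optimizable by back-propagation). Each channel is a four-stage
    shifted-window transformer (windowed multi-head self-attention with
    relative position bias, patch merging, depths 2/2/6/2); pooled features
    from both channels are concatenated and classified by a fully-connected
    softmax head under a cross-entropy loss. The package also provides the
    training augmentations (random flip, color jitter, Mixup, CutMix),
    stratified k-fold cross-validation, confusion-matrix metrics
    (accuracy/precision/recall/F1, macro and micro), a deterministic
    synthetic leaf-image generator for end-to-end testing, and import of
    pretrained backbone weights. All forward and backward passes are
    implemented in plain R; no GPU framework is required.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
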
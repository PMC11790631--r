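Package: florafusion
Title: Two-Stream Fusion of Front and Back Flower Views for Cultivar Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies flower specimens (e.g. medicinal chrysanthemum cultivars)
    from paired photographs of the front and the back of the inflorescence. The
    two views are processed by a two-stream residual convolutional network whose
    final stage exchanges information through cross-stream residual connections,
    and whose fully connected head fuses the streams by an asymmetric weighted
    sum before a joint classifier. Includes edge-detection-based background
    cropping, staged transfer-learning style training with a frozen shallow
    backbone, repeated stratified 6:2:2 evaluation with per-class stability
    metrics, ablation grids over the fusion components, gradient-weighted class
    activation maps, a t-SNE embedding of fused features, and a procedural
    generator of paired-view flower images whose class cues are deliberately
    split between the two views.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
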
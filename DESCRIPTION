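Package: octsr
Title: Unpaired Video Super-Resolution and Quality Metrics for Intra-Operative OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality enhancement of intra-operative optical coherence
    tomography (iOCT) video by unpaired video super-resolution. A
    bidirectional recurrent generator with optical-flow feature warping is
    trained adversarially against a pool of clean pre-operative OCT images,
    with a multilayer patchwise contrastive (InfoNCE) loss and a perceptual
    loss preserving the input's anatomy. Ships a speckle-degraded
    retina-phantom simulator for fully self-contained experiments, a
    no-reference evaluation suite (FID, KID, global contrast factor, fast
    noise estimation, k-NN precision/recall and density/coverage) plus
    full-reference PSNR/SSIM against synthetic ground truth, and a
    command-line pipeline (simulate, train, enhance, evaluate, ablate). The
    networks and their training run on a small built-in reverse-mode
    autodifferentiation engine over dense arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
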
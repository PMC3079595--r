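Package: historoi
Title: Supervised Saliency Detection of Diagnostic Regions in Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diagnostic regions of interest in haematoxylin-eosin
    histopathology fields with a supervised visual-attention model. Low-level
    conspicuity maps (intensity, colour double-opponency, Gabor orientation)
    and a local-entropy texture map are averaged inside regions produced by
    graph-based still-segmentation, combined linearly with learned channel
    weights, and thresholded against the mean region saliency. Segmentation
    parameters and feature weights are learned by generalized pattern search
    against a distance-weighted perceptual segmentation energy (boundary,
    over- and under-segmentation errors) computed from expert ground truth.
    Includes a synthetic-fixture generator emulating pale low-entropy stroma
    versus darker high-entropy carcinoma islets, pixel- and region-level
    evaluation, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
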
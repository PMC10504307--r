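Package: octasyn
Title: Synthesis of En Face OCT-Angiography from Fundus Photographs with
    Conditional Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to translate colour fundus photograph patches into en face
    OCT-angiography (OCT-A) patches with a compact conditional adversarial
    network (a U-Net generator against a convolutional discriminator), stitch
    full-field synthetic OCT-A images by sliding-window inference with overlap
    averaging, derive binary vessel maps by multiscale Hessian vesselness, and
    compute ETDRS-grid vessel-density biomarkers with correlation and
    precision-recall evaluation. Includes a procedural retinal phantom
    generator producing aligned fundus-like/OCT-A-like image pairs with
    ground-truth vessel masks, so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
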
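Package: efovct
Title: Extended Field-of-View CT Reconstruction by Sinogram Detruncation
    and Learned Projection Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates fan-beam CT acquisition of objects wider than the
    scan field of view (sFoV) and reconstructs them on an extended field
    of view (eFoV).  Implements two detruncation pipelines: HDFoV, which
    enforces per-projection mass consistency with a cosine-shaped
    extrapolation, binarizes a first-pass image and re-projects the
    object mask; and HDeepFoV, which forward-projects an image-domain
    estimate (identity, oracle, or a trained U-Net) and fuses it with
    the measured data in the projection domain.  Includes a procedural
    thorax-like phantom generator, a synthetic training-corpus
    generator, CPU training of a small U-Net with a structural
    dissimilarity (DSSIM) loss, and the quantitative evaluation
    protocol (eFoV-restricted Jaccard conformity, eFoV slice volumes,
    HU region statistics and histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
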
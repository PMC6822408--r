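Package: paniclecount
Title: Grain Number per Panicle from Rice Panicle Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image analysis pipeline for counting rice grains per detached
    panicle. Implements morphological preprocessing of scanner or camera
    images (Otsu segmentation, connected-component denoising, disk
    opening-based stem removal), extraction of three pixel-fraction features
    (coverage degree, skeleton, contour) per primary branch, min-max feature
    normalization, and univariate and multivariate linear regression counting
    models, together with naive component-counting baselines and a synthetic
    panicle-image generator with ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
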
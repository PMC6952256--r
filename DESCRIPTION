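Package: endofog
Title: Endoscopic Video Defogging by Luminance Blending
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Removes surgical smoke and fog from endoscopic video frames by
    fusing a contrast-enhancement branch with an atmospheric-veil visibility
    restoration branch in YCbCr luminance space. Includes the Koschmieder
    forward haze model and a synthetic smoke simulator for ground-truth
    benchmarking, joint bilateral and domain-transform recursive edge-aware
    filters, illumination-weighted luminance blending with histogram
    stretching, and a hybrid image-quality metric combining structural
    similarity with a statistical naturalness score.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
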
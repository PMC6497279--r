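Package: towcam
Title: Subsampling Design and Community Analysis for Towed-Camera Benthic Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating epibenthic community diversity from
    frame-by-frame annotations of towed-camera (camera sled) transect
    imagery, and for deciding how many frames are enough to annotate.
    Implements Shannon and Hill diversity indices at any taxonomic rank,
    systematic and random frame-subsampling designs, LOWESS-based plateau
    detection and a coefficient-of-variation stopping rule for sampling
    sufficiency, Ward minimum-variance clustering of community count
    matrices, tow geometry (cable layback, swept area), and a calibrated
    overdispersed (negative-binomial) synthetic frame-stream generator
    that emulates a 5 frames-per-second camera stream with multi-frame
    organism persistence. Ships the published summary tables of a
    Maryland wind-energy-area survey as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
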
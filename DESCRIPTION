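Package: cbctreg
Title: CT-to-CBCT Rigid Setup Correction for Prostate Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic three-dimensional intensity-based rigid registration of
    planning CT to treatment cone-beam CT (CBCT) scans for prostate setup
    correction in image-guided radiotherapy. Implements global, bony and local
    (margin-expanded clinical target volume) registration strategies driven by a
    masked, mean-subtracted normalized cross-correlation metric with a relaxed
    gradient-descent optimizer and a three-level multi-resolution pyramid;
    a replace-gas-by-tissue pre-processing filter; contour propagation with
    Dice and bidirectional-local-distance evaluation and a failure criterion;
    and a rectal-distension statistic computed from CT contours and gray values
    alone that predicts registration failure. A constructive-solid pelvis
    phantom generates paired CT/CBCT volumes with known ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
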
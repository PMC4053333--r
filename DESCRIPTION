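Package: vidtriage
Title: Pixel-Variation Triage of Camera-Trap Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated triage of camera-trap video recordings by the amount
    of pixel variation they contain. Two motion-energy filter statistics
    (deviation from the time-averaged frame, and frame-to-frame
    differencing) are reduced to a baseline-corrected scalar D per
    recording; recordings with D below a threshold are flagged as
    discardable non-target footage. The package builds the confusion
    matrix for the discard decision, sweeps thresholds into ROC curves,
    selects an operating point at a tolerated false-positive rate,
    computes the resulting screening-time savings, and quantifies the
    sampling stability of the false-positive rate with a bootstrap.
    Synthetic scene and D-population generators provide labeled test
    data with the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
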
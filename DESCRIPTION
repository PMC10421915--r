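Package: angiopipe
Title: Multi-Stage Automated Interpretation of Coronary Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully self-contained pipeline for automated
    interpretation of coronary angiogram cine runs: peak-contrast frame
    selection by structural similarity, classification of angiographic
    projection angle and primary anatomic structure with video-level
    aggregation and coronary gating, anchor-based localization of artery
    segments, stenoses and devices with IoU-based stenosis-to-segment
    assignment, percent-stenosis regression with hierarchical
    frame/video/artery averaging and an obstructive-disease threshold, a
    rule-based parser that extracts per-segment stenosis percentages from
    free-text procedure reports, a synthetic angiogram generator that
    renders contrast-filling vessel trees with known ground truth, and an
    agreement-metrics suite (classification reports, detection mAP, ROC
    AUC, ICC(2,2), Bland-Altman, subsample bootstrap confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
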
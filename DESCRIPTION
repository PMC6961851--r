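Package: handkin
Title: Kinematic Analysis of Rodent Food-Handling Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rodent food-handling from markerless
    pose-tracking trajectories and manually annotated ethograms. Reads
    pose-tracking tables in the DeepLabCut CSV export dialect, derives the
    snout-to-hands distance (L), inter-hand distance (D) and inter-D3 angle,
    recovers the two postural modes (oromanual and holding) by k-means
    clustering with L-method knee selection, detects rapid regrip and sniff
    maneuvers by peak prominence and slope criteria, characterizes regrip
    burst periodicity, bimanual asymmetry and grip-angle changes, estimates
    head pitch angle by Pratt's algebraic circle fit, and aggregates results
    with median/m.a.d. summaries and exact nonparametric rank tests. Includes
    a synthetic-session generator with full ground truth so every stage of
    the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
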
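Package: qimshelf
Title: Quality Index Method Shelf-Life Analysis for Ice-Stored Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensory shelf-life estimation of ice-stored fish with the
    Quality Index Method (QIM): demerit-scheme protocol handling and panel score
    aggregation, linear calibration of the quality index against days in ice with
    inverse prediction of storage time and remaining shelf-life, PLS1 (NIPALS)
    regression with VIP attribute-importance scores and leave-one-out validation,
    spoilage-indicator limit rules (microbial counts, TVB-N, TBARS, biogenic
    amines) with limit-crossing detection, an integrated shelf-life decision
    rule, and a synthetic spoilage/panel simulator so the whole pipeline can be
    exercised at desk scale. Ships a demerit protocol and reference calibrations
    for ice-stored king weakfish (Macrodon ancylodon).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
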
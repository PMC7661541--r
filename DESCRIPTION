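Package: birdstrikeR
Title: Birdstrike Risk Assessment for Airport Bird Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores birdstrike risk for every bird species recorded in an
    airport wildlife survey. From per-sighting observation tables (counts,
    flight heights, group sizes, activity zones) it assigns five risk
    factors (comparative number, comparative weight, flight-height
    coefficient, cluster coefficient, activity-range coefficient), combines
    them into 0-100 likelihood and severity scores, bands the scores, and
    classifies each species into one of three danger levels through a
    configurable 5x5 likelihood-severity risk matrix with rule-based
    adjustments for raptors and runway-crossing species. Includes seasonal
    risk reporting, cross-validation against historical strike records, a
    synthetic bird-community simulator emulating a monthly
    transect/point-count survey design, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
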
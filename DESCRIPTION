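Package: painsim
Title: Serious-Game Simulator and Evaluation Toolkit for Postoperative
    Pain Self-Management Education
Version: 0.1.0
Authors@R:
    person("painsim", "developers", email = "painsim@example.org",
           role = c("aut", "cre"))
Description: Headless re-implementation of the computational core of a
    serious game that teaches surgical patients postoperative pain
    self-management. Provides a discrete-time model of pain on the 0-10
    numeric rating scale with analgesic onset/peak/wash-out kinetics,
    side-effect triggers and pain-dependent mobility; a three-day game
    session with daily goals, 1-3 star ratings, random unmanageable-pain
    events and a help-line consult; append-only telemetry with an
    after-action-review timeline; declarative scoring of the AttrakDiff2,
    POP-MGS, BQ-II and PAK-PPM instruments; and the accompanying
    statistical battery (median/IQR, exact Wilcoxon signed-rank,
    Cronbach alpha, KR-20) together with scripted player policies and
    synthetic questionnaire respondents for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
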
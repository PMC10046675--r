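Package: brevis
Title: Scoring, Demographic Norms and Regression-Based Norming for the
    BReViS Visual-Search Test
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Broken Rings enVision Search (BReViS) four-card
    cancellation test: computes per-card performance times and the four
    attention indexes (Selective Attention, Orientation of Attention,
    Focal Attention, Total Errors), applies the published regression-based
    demographic corrections and classifies adjusted scores against
    published tolerance limits, equivalent scores and percentile norms.
    Also re-implements the full regression-based norming pipeline
    (interquartile-range outlier filtering, AICc-driven predictor
    transformation and model selection, reversed-coefficient correction
    regressions, nonparametric one-sided tolerance limits, rank-based
    equivalent scores and percentiles) so new normative datasets can be
    normed end to end, and ships a synthetic-cohort generator emulating
    the normative sample so every stage is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
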
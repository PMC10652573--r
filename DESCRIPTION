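Package: multisense
Title: Multisensory Integration Analysis for Redundant-Signals, Temporal
    Judgment and Flash-Illusion Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multisensory processing in behavioural
    intervention studies: race-model-inequality analysis of redundant-signals
    response times (Vincentized percentile binning, Miller-bound predicted
    CDFs, first-quartile AUC of the difference wave, and a max-t sign-flip
    permutation test), psychometric fitting of simultaneity and
    temporal-order judgments (Gaussian and logistic models yielding the point
    of subjective simultaneity and a temporal-binding-window proxy),
    sound-induced flash illusion accuracy scoring, session difference scores,
    and a tie-adjusted Friedman rank test. Includes exact builders for the
    four task designs and a trial-level synthetic-data generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
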
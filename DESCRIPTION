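Package: surgflow
Title: Task-Flow Analysis of Hierarchically Annotated Surgical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the structure of surgical tasks annotated with a
    hierarchical vocabulary of maneuvers and gestures. Reads tab-delimited
    annotation tables (gesture events with error flags, maneuver spans with
    incomplete flags, per-trial skill assessments), classifies trials by
    surgeon experience or by global rating score thresholds, and compares
    skill groups through segment-count statistics with percentile bootstrap
    intervals, first-order transition probability matrices, Hellinger
    distances between outgoing-transition distributions, conditional entropy
    of task flow, and Graphviz DOT state-flow exports. Includes
    inter-annotator reliability metrics (Levenshtein distance normalised per
    10 labels, frame-level Cohen's kappa by gesture category) and a
    skill-conditioned Markov generator of synthetic annotated datasets with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
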
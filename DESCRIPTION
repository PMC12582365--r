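Package: conceptdrift
Title: Temporal-Semantic Link Prediction for Biomedical Hypothesis Generation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models biomedical hypothesis generation as temporal link prediction on a
    dynamic concept co-occurrence graph. Per-concept semantic states, initialized from
    pre-computed language-model embeddings, evolve through a gated recurrent contextual
    integration step each time two concepts co-occur, and temporal multi-head
    cross-attention over a concept's neighborhood (keyed by first co-occurrence times)
    produces predictive embeddings that score future co-occurrences as candidate
    hypotheses. Includes construction of graphlet sequences from PubTator-style
    annotation records, chronological predict-then-update training with uniform
    negative sampling, AUC/AP evaluation with leakage removal, a synthetic dynamic
    graph generator with planted conceptual drift, and neighborhood-overlap and
    semantic-trajectory analysis tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
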
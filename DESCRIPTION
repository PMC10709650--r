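Package: megaccum
Title: Time-Resolved Zero-Shot Decoding of MEG Responses with Cumulative
    Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking the accumulation of visual and semantic
    information in event-related MEG responses. Maps concept x channel x
    time-bin response tensors to concept feature vectors (semantic word
    embeddings or visual network layer outputs) with leave-one-concept-out
    zero-shot ridge regression, using sliding, cumulative and
    cross-temporal analysis windows. Provides plateau and trough detection
    on prediction-target distance curves, label-permutation significance
    with false discovery rate correction, paired sliding-versus-cumulative
    comparisons, searchlight representational similarity analysis with
    cluster-based permutation testing, and group-level linear mixed
    modelling of plateau times. Includes a synthetic-data generator with
    configurable encoding dynamics and known ground-truth plateau times so
    that every analysis stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
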
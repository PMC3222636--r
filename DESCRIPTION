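Package: metamk
Title: Multi-Dimensional Meta-Knowledge Annotation for Biomedical Event Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enriching biomedical event corpora with multi-dimensional
    meta-knowledge annotation: a stand-off data model for events annotated with
    Knowledge Type, Certainty Level, Polarity, Manner and Source; readers and
    writers for a GENIA-style XML dialect and a line-oriented JSON interchange
    format; deterministic inference of the New Knowledge and Hypothesis
    hyper-dimensions; a clue-lexicon baseline tagger with a packaged lexicon of
    hedging, negation and manner cues; corpus distribution statistics;
    inter-annotator agreement (Cohen's kappa) with discrepancy reports; and a
    seeded synthetic-corpus generator that provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
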
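Package: biocloze
Title: Cloze-Style Biomedical Machine Comprehension with an Attention-Sum Reader
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds cloze-style question answering datasets from biomedical
    article records: dictionary-based entity tagging with MeSH-style entity
    resolution and type merging, entity-ID anonymization (global or local),
    candidate filtering, and title- or last-sentence question variants.
    Implements an attention-sum reader (bidirectional GRU context and query
    encoders, dot-product attention, pointer-sum aggregation) with optional
    pretrained word-embedding initialization and entity-type embeddings,
    trained by Adam with validation-based early stopping; probability-averaging
    ensembles; top-N accuracy evaluation and attention-heatmap export; and a
    synthetic corpus generator with planted answer cues for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    stringi,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
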
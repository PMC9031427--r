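Package: metaboText
Title: Metabolite Named Entity Recognition and Literature Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising metabolite names in full-text
    metabolomics articles. Implements a rule-based annotation pipeline
    (dictionary search, regular-expression partial matching with word
    expansion, and recursive span fix-ups), BIOES-tagged bidirectional
    LSTM sequence labellers with pluggable context-free or contextual
    token embeddings and a dictionary-trained name-internal
    pre-classifier, span-level evaluation (precision, recall, F1 and
    F*), document-level application to sections, tables and
    abbreviations, and article-weighted metabolite co-occurrence
    networks. Ships a deterministic synthetic-fixture generator so the
    whole stack can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
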
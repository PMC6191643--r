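Package: kintriage
Title: Literature Triage for Kinase Curation with Dictionary Annotation and Supervised Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for literature triage in protein-kinase database curation.
    Reads document collections in BioC XML (MEDLINE-style citations) or a
    simplified full-text XML, annotates documents with kinase and curation-axis
    (disease or biological-process) dictionaries by longest token-level match
    with synonym expansion, filters candidates by cross-reference validation,
    extracts engineered proximity features and bag-of-words 2-/3-gram TFIDF
    features, ranks documents per (kinase, axis) topic with a margin-based or
    elastic-net scorer trained on gold positives plus pseudo-negatives, and
    evaluates rankings with the TREC metric suite (precision and recall at
    fixed ranks, maximum precision, average precision, R-precision) under
    trec_eval conventions. Includes a synthetic-benchmark generator with a
    planted co-mention signal so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    Matrix,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
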
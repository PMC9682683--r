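Package: gatner
Title: Biomedical Named Entity Recognition with Graph Attention Networks
    over Dependency Parses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models each sentence as an attributed graph built from its
    dependency parse and casts BIO sequence labeling as node
    classification.  Per-token features fuse a contextual embedding with
    a 54-dimensional one-hot syntactic encoding (part-of-speech block
    plus separate in-degree and out-degree slots per dependency
    relation).  Nodes are classified with a multi-head graph attention
    network and a softmax decoder, trained by backpropagation with an
    adaptive first-order optimizer.  Includes readers and writers for
    two-column BIO CoNLL and CoNLL-U corpora, strict entity-level
    precision/recall/F1 scoring with complete-span matching, a seeded
    synthetic treebank generator for dependency-parsed, BIO-labeled
    corpora, and a reproducible simulate/train/predict/evaluate
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
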
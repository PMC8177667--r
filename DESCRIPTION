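Package: seqchunk
Title: Chunk Recoding and Representational Similarity Analysis for Visual
    Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for contrasting associative and recoding (chunking) accounts
    of visual sequence learning. Implements item-position (Hamming), item-item
    (n-gram) and item-mixture sequence representation models; a Bayesian
    chunk-learning model with combinatorial n-gram priors, parse enumeration
    and model-evidence ranking; constraint-satisfying experimental design
    generation with Monte-Carlo search; representational similarity analysis
    (RSA) with noise ceilings and permutation-based group inference;
    model-free pattern-distance dynamics; a combinatorial interference and
    capacity analysis; and a synthetic multi-subject voxel-pattern generator
    so that every analysis can be exercised end-to-end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
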
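Package: dyadnet
Title: Dyadic-Effect Analysis of Binary Node Metadata in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how binary node metadata correlate with the
    structure of an undirected network through the dyadic effect. Counts
    the three dyad (edge) types induced by a binary node label, compares
    them with their random-assignment expectations and with exact
    degree-sequence bounds, and summarises the departure from randomness
    through dyadicity and heterophilicity. A geometric relevance score
    built on the bounded H-D space ranks competing metadata, label
    permutation tests attach significance to each score, and cosine
    similarity between label vectors measures metadata redundancy
    (the Redundancy-Relevance diagram). Includes an exact phase-diagram
    enumerator for small networks that serves as a brute-force oracle,
    deterministic synthetic-network generators, and report writers for
    tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
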
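Package: esagraph
Title: Edge-Set Attention for Graph Learning
Version: 0.1.0
Authors@R: person("Analysis", "Engineering", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Graph representation learning that treats a graph as a set of
    edge tokens processed by interleaved masked and vanilla self-attention
    blocks, with attention-based pooling (learnable seed vectors) for
    graph-level outputs and a node-token variant for node classification.
    Includes exact batched construction of edge- and node-adjacency attention
    masks, seeded synthetic-task generators (Erdos-Renyi counting and
    shortest-path tasks, 1-WL-hard line-graph fixtures), a pure-R training
    harness with Adam, and attention-score extraction with Gini concentration
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
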
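Package: motifquery
Title: Declarative Motif Queries, Census and Null Models for Attributed Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative query language and search engine for small subgraph
    patterns ("motifs") in attributed directed graphs such as connectomes.
    Motif queries written in a compact text DSL (directed edges, forbidden
    edges, node and edge attribute constraints, macros, interchangeability
    declarations) are parsed, validated for logical and biological
    consistency, optimized via automorphism detection and symmetry breaking,
    and executed with a queue-based subgraph monomorphism/isomorphism search.
    Includes transpilation of queries to Cypher text, five density-calibrated
    random-graph null models (Erdos-Renyi, random geometric, Watts-Strogatz,
    Barabasi-Albert, degree-preserving X-swap), exhaustive enumeration of
    small undirected and directed motif classes, and census tooling for
    comparing motif counts against null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
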
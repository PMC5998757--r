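Package: litpath
Title: Literature-Mined Co-Occurrence Networks and Node Embeddings for
    Pathway Link Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sentence-level gene co-occurrence networks from
    PubMed-style abstract collections, learns node embeddings with
    node2vec (second-order biased random walks plus skip-gram with
    negative sampling; DeepWalk as the uniform-walk special case),
    ranks candidate interaction partners by cosine similarity, and
    evaluates captured links against KEGG-style pathway models in
    which indirect interactions are expanded into chains of direct
    links through auxiliary pathways. Includes a synthetic-corpus
    generator with a planted ground-truth network so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
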
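#!/usr/bin/env Rscript

# Stage 3: learn node2vec (p = 1, q = 0.5) and DeepWalk (p = q = 1)
# embeddings from the mined co-occurrence network with shared parameters
# d = 128, r = l = 10, k = 10.

suppressPackageStartupMessages(library(litpath))

seed <- 20260929L
out <- "results/synthetic"
dict <- read_dictionary_tsv(file.path(out, "dictionary.tsv"))
graph <- read_edgelist_tsv(file.path(out, "cooccurrence_edges.tsv"), dict)

wcfg <- walk_config(seed = seed + 2L)
tcfg <- train_config(seed = seed + 3L)

walks <- simulate_walks(graph, wcfg)
write_walks(walks, file.path(out, "walks_node2vec.txt"))
emb_n2v <- train_skipgram(walks, tcfg)
emb_dw <- deepwalk_embed(graph, wcfg, tcfg)

write_embeddings(emb_n2v, file.path(out, "embedding_node2vec.txt"))
write_embeddings(emb_dw, file.path(out, "embedding_deepwalk.txt"))

message(sprintf("embedded %d nodes in %d dimensions (%d walks of <= %d nodes)",
                nrow(emb_n2v), ncol(emb_n2v), length(walks), wcfg$l))
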
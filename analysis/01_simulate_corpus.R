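#!/usr/bin/env Rscript

# Stage 1: plant a ground-truth gene network and synthesize the abstract
# corpus whose sentence-level co-mentions encode it.
#
# Conditions: 30 genes in 3 blocks (planted-partition, p_in = 0.5,
# p_out = 0.05), 2 hidden genes that never appear in abstracts (their edges
# become the zero-co-mention pairs), 2,000 abstracts x 8 sentences,
# lambda_direct = 50 co-mentions per true edge, lambda_noise = 0.5 per
# background pair.

suppressPackageStartupMessages(library(litpath))

seed <- 20260929L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

net <- planted_block_network(seed = seed)
dict <- synthetic_gene_dictionary(net$genes)
corpus <- generate_corpus(net, corpus_config(seed = seed + 1L), dict)

write_network_tsv(net, file.path(out, "planted_network.tsv"))
write_pathway_json(planted_truth_pathway(net),
                   file.path(out, "truth_pathway.json"))
write_dictionary_tsv(dict, file.path(out, "dictionary.tsv"))
write_corpus_tsv(corpus, file.path(out, "corpus.tsv"))
write_pubmed_xml(corpus, file.path(out, "corpus.xml"))

message(sprintf("planted %d genes, %d true edges (%d suppressed as absent), %d hidden genes",
                length(net$genes), nrow(net$edges), nrow(net$absent_pairs),
                length(net$hidden_genes)))
message(sprintf("wrote %d abstracts to %s", nrow(corpus), out))
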
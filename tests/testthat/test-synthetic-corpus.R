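test_that("planted network validates its invariants", {
  edges <- data.frame(start = c("A", "B"), target = c("B", "C"),
                      stringsAsFactors = FALSE)
  net <- planted_network(c("A", "B", "C"), edges)
  expect_s3_class(net, "planted_network")
  expect_error(planted_network(c("A", "B"), data.frame(start = "A",
                                                       target = "A")),
               "self-edges")
  expect_error(planted_network(c("A", "B"), data.frame(start = "A",
                                                       target = "Z")),
               "endpoint")
  expect_error(
    planted_network(c("A", "B", "C"), edges,
                    absent_pairs = data.frame(start = "A", target = "C")),
    "subset of edges")
  # hidden genes force their incident edges into absent_pairs
  net_h <- planted_network(c("A", "B", "C"), edges, hidden_genes = "C")
  expect_equal(nrow(net_h$absent_pairs), 1)
  expect_setequal(unlist(net_h$absent_pairs), c("B", "C"))
})

test_that("corpus generation is deterministic and respects the contract", {
  st <- tiny_study()
  expect_equal(nrow(st$corpus), st$cfg$n_abstracts)
  expect_false(anyDuplicated(st$corpus$pmid) > 0)
  expect_true(all(nzchar(st$corpus$abstract)))
  again <- generate_corpus(st$net, st$cfg, st$dict)
  expect_identical(st$corpus, again)
  other <- generate_corpus(st$net,
                           corpus_config(n_abstracts = 60,
                                         sentences_per_abstract = 5,
                                         lambda_direct = 25,
                                         lambda_noise = 0, seed = 999),
                           st$dict)
  expect_false(identical(st$corpus, other))
})

test_that("a gene without a dictionary entry is a configuration error", {
  net <- planted_network(c("A", "B"),
                         data.frame(start = "A", target = "B"))
  dict <- synthetic_gene_dictionary("A")
  expect_error(generate_corpus(net, corpus_config(seed = 1), dict),
               "dictionary entry")
  expect_error(corpus_config(lambda_direct = -1), "positive")
  expect_error(corpus_config(lambda_noise = -0.1), "nonnegative")
})

test_that("with a single positive-rate pair every co-mention is that pair", {
  genes <- c("GA", "GB", "GC")
  net <- planted_network(genes,
                         data.frame(start = "GA", target = "GB"))
  dict <- synthetic_gene_dictionary(genes)
  cfg <- corpus_config(n_abstracts = 40, sentences_per_abstract = 5,
                       lambda_direct = 30, lambda_noise = 0,
                       singleton_prob = 0.3, seed = 7)
  corpus <- generate_corpus(net, cfg, dict)
  counts <- scan_comention_counts(corpus, genes)
  expect_gt(counts["GA", "GB"], 0)
  others <- counts[upper.tri(counts)]
  expect_equal(sum(others) - counts["GA", "GB"], 0)
})

test_that("absent pairs never co-occur in any sentence", {
  genes <- sprintf("G%02d", 1:6)
  edges <- data.frame(start = genes[c(1, 2, 3, 4, 5)],
                      target = genes[c(2, 3, 4, 5, 6)],
                      stringsAsFactors = FALSE)
  net <- planted_network(genes, edges,
                         absent_pairs = data.frame(start = "G03",
                                                   target = "G04"))
  dict <- synthetic_gene_dictionary(genes)
  corpus <- generate_corpus(net,
                            corpus_config(n_abstracts = 150,
                                          sentences_per_abstract = 6,
                                          lambda_direct = 40,
                                          lambda_noise = 0.5, seed = 3),
                            dict)
  counts <- scan_comention_counts(corpus, genes)
  expect_equal(counts["G03", "G04"], 0)
  # live edges are all present
  expect_true(all(counts[cbind(c("G01", "G02", "G04", "G05"),
                               c("G02", "G03", "G05", "G06"))] > 0))
})

test_that("co-mention counts recover the configured Poisson rates", {
  genes <- sprintf("G%02d", 1:11)
  edges <- data.frame(start = genes[1:10], target = genes[2:11],
                      stringsAsFactors = FALSE)  # 10-edge path
  net <- planted_network(genes, edges)
  dict <- synthetic_gene_dictionary(genes)
  corpus <- generate_corpus(net,
                            corpus_config(n_abstracts = 400,
                                          sentences_per_abstract = 8,
                                          lambda_direct = 50,
                                          lambda_noise = 0, seed = 17),
                            dict)
  counts <- scan_comention_counts(corpus, genes)
  edge_counts <- counts[cbind(edges$start, edges$target)]
  # mean over 10 edges within 3 standard errors of lambda = 50
  se <- sqrt(50 / nrow(edges))
  expect_lt(abs(mean(edge_counts) - 50), 3 * se)
})

test_that("hidden genes leave no trace in the corpus", {
  genes <- sprintf("G%02d", 1:6)
  edges <- data.frame(start = genes[c(1, 2, 3, 4, 5)],
                      target = genes[c(2, 3, 4, 5, 6)],
                      stringsAsFactors = FALSE)
  net <- planted_network(genes, edges, hidden_genes = "G06")
  dict <- synthetic_gene_dictionary(genes)
  corpus <- generate_corpus(net,
                            corpus_config(n_abstracts = 120,
                                          sentences_per_abstract = 6,
                                          lambda_direct = 30,
                                          lambda_noise = 1,
                                          singleton_prob = 0.5, seed = 5),
                            dict)
  all_text <- paste(corpus$title, corpus$abstract, collapse = " ")
  expect_false(grepl("G06", all_text, fixed = TRUE))
})

test_that("the truth pathway mirrors the planted network and a perfect corpus recovers it", {
  st <- tiny_study()
  pw <- planted_truth_pathway(st$net)
  expect_s3_class(pw, "pathway")
  expect_equal(nrow(pw$edges), nrow(st$net$edges))
  expect_true(all(pw$edges$interaction == "direct"))
  expect_true(all(pw$entities$type == "gene"))
  # empty edge set
  empty <- planted_truth_pathway(planted_network(
    "A", data.frame(start = character(0), target = character(0))))
  expect_equal(nrow(empty$edges), 0)
  # the co-occurrence baseline on a noise-free corpus captures every
  # non-absent planted edge
  g <- build_cooccurrence_graph(st$corpus, st$dict)
  tbl <- cooccurrence_rank_table(g, planted_pairs(st$net)[, 1:2], K = 10)
  expect_equal(capture_count(tbl), nrow(st$net$edges))
})
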
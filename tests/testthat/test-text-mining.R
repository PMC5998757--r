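test_that("sentence splitting handles terminators, abbreviations and recovers the text", {
  expect_identical(split_sentences(""), character(0))
  expect_identical(split_sentences("   "), character(0))
  expect_length(split_sentences("A binds B. C binds D."), 2)
  # hand-segmented cases: abbreviations must not split
  cases <- list(
    list(text = "Insulin acts downstream, i.e. after receptor binding. IRS1 is next.",
         n = 2),
    list(text = "Several kinases (e.g. AKT) were profiled. Results follow.",
         n = 2),
    list(text = "Smith et al. reported this effect. We confirmed it.",
         n = 2),
    list(text = "See Fig. 2 for details. The pathway is shown there.",
         n = 2),
    list(text = "Is insulin involved? Yes! It binds INSR.", n = 3))
  for (cs in cases) {
    got <- split_sentences(cs$text)
    expect_length(got, cs$n)
    expect_identical(paste(got, collapse = " "),
                     gsub("\\s+", " ", trimws(cs$text)))
  }
})

test_that("mention extraction matches an exhaustive brute-force matcher", {
  dict <- gene_dictionary(
    c("INSR", "IRS1/IRS", "TNFA", "GLP-1", "INS"),
    synonyms = list(c("INSR", "insulin receptor"),
                    c("IRS1", "IRS"),
                    c("TNF-alpha", "TNF"),
                    c("GLP-1"),
                    c("insulin", "INS")))
  sentences <- c(
    "The insulin receptor activates IRS1 in muscle",
    "IRS but not IRS2 binds TNF-alpha",
    "insulin and GLP-1 share no receptor with TNF",
    "INSULIN RECEPTOR and irs1 are case-insensitive",
    "Nothing relevant is mentioned here",
    "TNF-alpha-induced signaling involves IRS",  # hyphen-flanked token
    "insulin insulin insulin",                   # repeats collapse to one id
    "IRS1/IRS is never written verbatim but IRS1 is")
  for (s in sentences) {
    got <- sort(unique(extract_mentions(s, dict)$canonical_id))
    expect_identical(got, oracle_mentions(s, dict), label = s)
  }
})

test_that("longest match wins over contained synonyms", {
  dict <- gene_dictionary(c("IRS1/IRS", "INSR"),
                          synonyms = list(c("IRS1", "IRS"),
                                          c("insulin receptor substrate")))
  m <- extract_mentions("IRS1 was phosphorylated", dict)
  expect_identical(m$surface_form, "IRS1")
  # "insulin receptor substrate" must not also fire its prefix inside
  m2 <- extract_mentions("the insulin receptor substrate level rose", dict)
  expect_identical(m2$canonical_id, "INSR")
})

test_that("extraction is idempotent and casing-insensitive", {
  dict <- gene_dictionary(c("TNFA"), synonyms = list(c("TNF-alpha")))
  s <- "TNF-ALPHA and tnf-alpha and Tnf-Alpha"
  m1 <- extract_mentions(s, dict)
  m2 <- extract_mentions(s, dict)
  expect_identical(m1, m2)
  expect_identical(m1$canonical_id, "TNFA")
})

test_that("co-occurrence edges count co-mentioning sentences only", {
  dict <- gene_dictionary(c("A1", "B1", "C1"))
  recs <- data.frame(
    pmid = c("p1", "p2", "p3"),
    title = c("no genes", "no genes", "no genes"),
    abstract = c(
      "A1 binds B1.",                              # one co-mention
      "A1 binds B1. A1 binds B1. A1 binds B1.",    # three more
      "A1 acts alone. B1 acts alone. C1 too."),    # same abstract, no edge
    stringsAsFactors = FALSE)
  g <- build_cooccurrence_graph(recs, dict)
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 4)
  expect_true(all(c("A1", "B1", "C1") %in% igraph::V(g)$name))
  # empty corpus
  g0 <- build_cooccurrence_graph(recs[0, ], dict)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("title mentions count as sentence 0 and can be disabled", {
  dict <- gene_dictionary(c("A1", "B1"))
  recs <- data.frame(pmid = "p1", title = "A1 regulates B1",
                     abstract = "Nothing else here.",
                     stringsAsFactors = FALSE)
  g <- build_cooccurrence_graph(recs, dict)
  expect_equal(igraph::ecount(g), 1)
  g2 <- build_cooccurrence_graph(recs, dict, include_titles = FALSE)
  expect_equal(igraph::ecount(g2), 0)
})

test_that("graph weights are symmetric and total weight equals co-mention incidences", {
  st <- tiny_study()
  g <- build_cooccurrence_graph(st$corpus, st$dict)
  counts <- scan_comention_counts(st$corpus, st$net$genes)
  ed <- igraph::as_data_frame(g, what = "edges")
  for (k in seq_len(nrow(ed))) {
    expect_equal(ed$weight[k], counts[ed$from[k], ed$to[k]])
    expect_equal(counts[ed$from[k], ed$to[k]], counts[ed$to[k], ed$from[k]])
  }
  expect_equal(sum(ed$weight), sum(counts) / 2)
})

test_that("co-occurrence ranking sorts by weight with lexicographic ties", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("S", "S", "S", "S"),
               to = c("B", "C", "A", "D"),
               weight = c(7, 7, 2, 9)),
    directed = FALSE)
  igraph::V(g)$category <- "gene"
  igraph::V(g)$semantic_type <- "Gene or Genome"
  tk <- cooccurrence_topk(g, "S", K = 100, type_filter = "gene")
  expect_identical(tk$entity, c("D", "B", "C", "A"))
  expect_identical(tk$rank, 1:4)
  expect_identical(cooccurrence_topk(g, "S", K = 2)$entity, c("D", "B"))
  expect_error(cooccurrence_topk(g, "ZZ"), "not in graph")
  # no neighbors
  g2 <- igraph::add_vertices(g, 1, name = "L", category = "gene",
                             semantic_type = "Gene or Genome")
  expect_equal(nrow(cooccurrence_topk(g2, "L")), 0)
})

test_that("absent pairs produce no co-occurrence edge", {
  genes <- c("GA", "GB", "GC")
  net <- planted_network(
    genes,
    data.frame(start = c("GA", "GB"), target = c("GB", "GC")),
    absent_pairs = data.frame(start = "GB", target = "GC"))
  dict <- synthetic_gene_dictionary(genes)
  corpus <- generate_corpus(net,
                            corpus_config(n_abstracts = 80,
                                          sentences_per_abstract = 5,
                                          lambda_direct = 30,
                                          lambda_noise = 0, seed = 9),
                            dict)
  g <- build_cooccurrence_graph(corpus, dict)
  expect_false(igraph::are_adjacent(g, "GB", "GC"))
  expect_true(igraph::are_adjacent(g, "GA", "GB"))
})
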
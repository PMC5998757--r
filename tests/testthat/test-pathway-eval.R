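fx <- load_t2d_fixture()

test_that("the encoded pathway tables carry the published structure", {
  expect_equal(nrow(fx$pathway$entities), 19)
  expect_equal(nrow(fx$pathway$edges), 18)
  expect_equal(sum(fx$pathway$edges$interaction == "indirect"), 9)
  expect_equal(sum(fx$pathway$edges$interaction == "direct"), 9)
  expect_equal(nrow(fx$rank_table), 30)
  expect_equal(sum(is.na(fx$rank_table$node2vec)), 5)
  expect_equal(nrow(fx$extra_undirected), 5)
})

test_that("indirect interactions expand to the published 30 direct links", {
  ex <- expand_indirect_paths(fx$pathway)
  expect_equal(nrow(ex), 30)
  expect_setequal(paste(ex$start, ex$target),
                  paste(fx$rank_table$start, fx$rank_table$target))
  # the original direct edges are a subset of the expansion output
  direct <- fx$pathway$edges[fx$pathway$edges$interaction == "direct", ]
  expect_true(all(paste(direct$source, direct$target) %in%
                    paste(ex$start, ex$target)))
  # a receptor-to-kinase cascade contributes 7 consecutive links
  chain7 <- fx$expansions[[2]]
  expect_equal(length(chain7$chain) - 1, 7)
  # pathway with no indirect edges passes through unchanged
  pw0 <- planted_truth_pathway(planted_network(
    c("A", "B"), data.frame(start = "A", target = "B")))
  ex0 <- expand_indirect_paths(pw0)
  expect_identical(ex0[, c("start", "target")],
                   data.frame(start = "A", target = "B"))
})

test_that("expansion chains referencing direct edges are rejected", {
  bad <- list(source = "INS", target = "INSR",
              chain = c("INS", "X", "INSR"))
  expect_error(expand_indirect_paths(fx$pathway, list(bad)),
               "direct edge")
  miss <- list(source = "INS", target = "GLUT4",
               chain = c("INS", "X", "GLUT4"))
  expect_error(expand_indirect_paths(fx$pathway, list(miss)), "missing")
})

test_that("capture and within-rank counts reproduce the published totals", {
  n2 <- t2d_rank_records(fx$rank_table, "node2vec")
  co <- t2d_rank_records(fx$rank_table, "cooccurrence")
  dw <- t2d_rank_records(fx$rank_table, "deepwalk")
  expect_equal(capture_count(n2), 25)
  expect_equal(capture_count(co), 22)
  expect_equal(capture_count(dw), 23)
  expect_equal(within_rank_count(n2, 10), 24)
  # threshold = K degenerates to the capture count
  expect_equal(within_rank_count(n2, 100), capture_count(n2))
  # rank-1 rows by direct scan
  expect_equal(within_rank_count(n2, 1),
               sum(fx$rank_table$node2vec == 1, na.rm = TRUE))
  # monotone in the threshold
  counts <- vapply(1:100, function(t) within_rank_count(n2, t), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(within_rank_count(n2, 0), ">= 1")
})

test_that("head-to-head comparison reproduces the published win/loss/tie triples", {
  n2 <- t2d_rank_records(fx$rank_table, "node2vec")
  co <- t2d_rank_records(fx$rank_table, "cooccurrence")
  dw <- t2d_rank_records(fx$rank_table, "deepwalk")
  vs_co <- head_to_head(n2, co)
  expect_equal(c(vs_co$wins, vs_co$losses, vs_co$ties), c(9, 4, 9))
  vs_dw <- head_to_head(n2, dw)
  expect_equal(c(vs_dw$wins, vs_dw$losses, vs_dw$ties), c(8, 1, 14))
  # antisymmetry and the tie identity
  rev <- head_to_head(co, n2)
  expect_equal(rev$wins, vs_co$losses)
  expect_equal(rev$losses, vs_co$wins)
  expect_equal(rev$ties, vs_co$ties)
  self <- head_to_head(n2, n2)
  expect_equal(self$wins + self$losses, 0)
  expect_equal(self$ties, self$n_compared)
  expect_error(head_to_head(n2, co[1:10, ]), "different")
})

test_that("the extended network has the published size and hub", {
  ex <- expand_indirect_paths(fx$pathway)
  net <- build_extended_network(ex, fx$extra_undirected)
  expect_equal(igraph::vcount(net), 29)
  expect_equal(igraph::ecount(net), 35)
  dc <- degree_centrality(net)
  expect_equal(unname(dc["IRS1/IRS"]), 8L)
  expect_equal(names(which.max(dc)), "IRS1/IRS")
  hub_nb <- names(igraph::neighbors(net, "IRS1/IRS"))
  expect_setequal(hub_nb, c("INSR", "PI3K", "SOCS", "IKK", "JNK", "PKCZ",
                            "PKCD/E", "GRB2"))
  # duplicates collapse; empty input gives an empty graph
  dup <- build_extended_network(
    data.frame(start = c("X", "X"), target = c("Y", "Y")),
    data.frame(a = "Y", b = "X"))
  expect_equal(igraph::ecount(dup), 1)
  empty <- build_extended_network(data.frame(start = character(0),
                                             target = character(0)))
  expect_equal(igraph::vcount(empty), 0)
})

test_that("degree centrality counts incident edges regardless of direction", {
  star <- igraph::graph_from_data_frame(
    data.frame(from = "HUB", to = c("A", "B", "C", "D")),
    directed = FALSE)
  dc <- degree_centrality(star)
  expect_equal(unname(dc["HUB"]), 4L)
  expect_true(all(dc[c("A", "B", "C", "D")] == 1))
  single <- build_extended_network(data.frame(start = "A", target = "B"))
  expect_true(all(degree_centrality(single) == 1))
})

test_that("pathways round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  write_pathway_json(fx$pathway, f)
  back <- read_pathway_json(f)
  expect_equal(back$entities, fx$pathway$entities)
  expect_equal(back$edges, fx$pathway$edges)
  expect_equal(length(back$expansions), length(fx$pathway$expansions))
  expect_identical(
    expand_indirect_paths(back),
    expand_indirect_paths(fx$pathway))
})

test_that("malformed rank tables report the offending row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("direct_no\tstart\ttarget\tnode2vec",
               "1\tA\tB\t3",
               "2\tB\tC\toops"), f)
  expect_error(read_t2d_rank_table(f), "row 2")
})

test_that("evaluation summaries aggregate captures per method", {
  n2 <- t2d_rank_records(fx$rank_table, "node2vec")
  dw <- t2d_rank_records(fx$rank_table, "deepwalk")
  sm <- evaluation_summary(list(node2vec = n2, deepwalk = dw),
                           threshold = 10)
  expect_equal(sm$captured, c(25, 23))
  expect_equal(sm$within_threshold[1], 24)
  expect_equal(sm$n_links, c(30, 30))
})
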
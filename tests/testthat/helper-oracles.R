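# Independent oracles and shared fixtures. Everything here is computed by
# enumeration or naive scanning, never through the code paths under test.

# Exact second-order transition distribution for every directed (prev, cur)
# pair, by direct enumeration of the bias rule over cur's neighbors.
oracle_second_order <- function(graph, p, q, weighted = TRUE) {
  nm <- igraph::V(graph)$name
  out <- list()
  for (cur in nm) {
    nbs <- names(igraph::neighbors(graph, cur))
    if (length(nbs) == 0) next
    for (prev in nbs) {
      w <- numeric(length(nbs))
      for (i in seq_along(nbs)) {
        x <- nbs[i]
        alpha <- if (x == prev) 1 / p
        else if (igraph::are_adjacent(graph, prev, x)) 1
        else 1 / q
        ew <- if (weighted)
          igraph::E(graph)$weight[igraph::get_edge_ids(graph, c(cur, x))]
        else 1
        w[i] <- alpha * ew
      }
      out[[paste(prev, cur, sep = "|")]] <- stats::setNames(w / sum(w), nbs)
    }
  }
  out
}

# Exact first-order (weight-proportional) transition distribution per node.
oracle_first_order <- function(graph, weighted = TRUE) {
  out <- list()
  for (cur in igraph::V(graph)$name) {
    nbs <- names(igraph::neighbors(graph, cur))
    if (length(nbs) == 0) next
    w <- vapply(nbs, function(x) {
      if (weighted)
        igraph::E(graph)$weight[igraph::get_edge_ids(graph, c(cur, x))]
      else 1
    }, numeric(1))
    out[[cur]] <- w / sum(w)
  }
  out
}

# (prev, cur, next) triples pooled over a walk corpus.
walk_triples <- function(walks) {
  take <- function(w, k) {
    n <- length(w)
    if (n >= 3) w[k:(n - 3 + k)] else character(0)
  }
  data.frame(prev = unlist(lapply(walks, take, 1)),
             cur = unlist(lapply(walks, take, 2)),
             nxt = unlist(lapply(walks, take, 3)),
             stringsAsFactors = FALSE)
}

# Largest per-cell z-score of empirical conditional transition frequencies
# against the enumerated second-order distribution; also returns the number
# of sampled steps.
second_order_max_z <- function(graph, p, q, weighted, seed,
                               min_steps = 1e5) {
  n <- igraph::vcount(graph)
  l <- 12L
  r <- ceiling(min_steps / (n * (l - 2)))
  walks <- simulate_walks(
    graph, walk_config(p = p, q = q, r = r, l = l, weighted = weighted,
                       seed = seed))
  tri <- walk_triples(walks)
  exact <- oracle_second_order(graph, p, q, weighted)
  key <- paste(tri$prev, tri$cur, sep = "|")
  max_z <- 0
  for (k in names(exact)) {
    sel <- key == k
    n_k <- sum(sel)
    if (n_k == 0) next
    probs <- exact[[k]]
    obs <- table(factor(tri$nxt[sel], levels = names(probs)))
    z <- abs(as.numeric(obs) / n_k - probs) /
      sqrt(pmax(probs * (1 - probs), 1e-12) / n_k)
    max_z <- max(max_z, z)
  }
  list(max_z = max_z, n_steps = nrow(tri))
}

# Exhaustive naive mention matcher: every boundary-valid substring match of
# every synonym, then greedy longest-match-first span claiming. Returns the
# set of canonical ids.
oracle_mentions <- function(sentence, dictionary) {
  low <- tolower(sentence)
  nc <- nchar(sentence)
  id <- character(0); st <- integer(0); en <- integer(0)
  for (cid in dictionary$ids) {
    for (syn in dictionary$synonyms[[cid]]) {
      ls <- tolower(syn)
      L <- nchar(ls)
      if (L > nc || L == 0) next
      for (i in seq_len(nc - L + 1)) {
        if (substr(low, i, i + L - 1) != ls) next
        okl <- i == 1 ||
          !grepl("[[:alnum:]]", substr(sentence, i - 1, i - 1))
        okr <- i + L - 1 == nc ||
          !grepl("[[:alnum:]]", substr(sentence, i + L, i + L))
        if (okl && okr) {
          id <- c(id, cid); st <- c(st, i); en <- c(en, i + L - 1L)
        }
      }
    }
  }
  if (length(id) == 0) return(character(0))
  ord <- order(-(en - st), st)
  claimed <- rep(FALSE, nc)
  keep <- character(0)
  for (k in ord) {
    span <- st[k]:en[k]
    if (any(claimed[span])) next
    claimed[span] <- TRUE
    keep <- c(keep, id[k])
  }
  sort(unique(keep))
}

# Naive sentence scanner counting, for each gene pair, the sentences that
# contain tokens of both genes (synthetic-dictionary surface forms share the
# gene id as token).
scan_comention_counts <- function(corpus, genes) {
  sents <- unlist(lapply(seq_len(nrow(corpus)), function(i) {
    c(corpus$title[i],
      strsplit(corpus$abstract[i], "(?<=[.!?])\\s+", perl = TRUE)[[1]])
  }))
  pres <- vapply(genes, function(g)
    grepl(paste0("(^|[^[:alnum:]])", g, "([^[:alnum:]]|$)"), sents),
    logical(length(sents)))
  counts <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1):length(genes)) {
      counts[i, j] <- counts[j, i] <- sum(pres[, i] & pres[, j])
    }
  }
  counts
}

# Small named graphs for walk tests; all edges weight 1 unless given.
named_graph <- function(edges, weights = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::E(g)$weight <- if (is.null(weights)) rep(1, igraph::ecount(g))
  else weights
  g
}

triangle_with_tail <- function() {
  named_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D")))
}

# Two-direction asymmetric embedding: B is A's nearest neighbor, but from B
# the cluster C1..C3 crowds A out.
angle_embedding <- function() {
  deg <- c(A = 0, B = 40, C1 = 45, C2 = 50, C3 = 55)
  emb <- t(vapply(deg * pi / 180, function(a) c(cos(a), sin(a)),
                  numeric(2)))
  rownames(emb) <- names(deg)
  emb
}

# Tiny deterministic corpus for smoke tests: 4 genes on a square.
tiny_study <- function(seed = 101) {
  genes <- c("GA", "GB", "GC", "GD")
  net <- planted_network(
    genes,
    data.frame(start = c("GA", "GB", "GC", "GD"),
               target = c("GB", "GC", "GD", "GA"),
               stringsAsFactors = FALSE))
  dict <- synthetic_gene_dictionary(genes)
  cfg <- corpus_config(n_abstracts = 60, sentences_per_abstract = 5,
                       lambda_direct = 25, lambda_noise = 0,
                       seed = seed)
  list(net = net, dict = dict, cfg = cfg,
       corpus = generate_corpus(net, cfg, dict))
}
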
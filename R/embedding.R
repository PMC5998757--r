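#' Walk configuration
#'
#' Parameters of the second-order biased random walk. Defaults are the
#' settings used throughout this package's analyses: return parameter
#' `p = 1`, in-out parameter `q = 0.5` (favoring homophily / community
#' structure), `r = 10` walks per node of length `l = 10` nodes, transitions
#' weighted by co-occurrence counts.
#'
#' @param p Return parameter (> 0); a step back to the previous node is
#'   biased by `1/p`.
#' @param q In-out parameter (> 0); a step to a node at distance 2 from the
#'   previous node is biased by `1/q`.
#' @param r Walks started per node (>= 1).
#' @param l Walk length counted in nodes (>= 2), so `l` nodes = `l - 1` steps.
#' @param weighted Multiply transition biases by edge weights.
#' @param seed Integer seed for walk-order shuffling and step sampling.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 1, q = 0.5, r = 10, l = 10, weighted = TRUE,
                        seed = 1L) {
  if (!is.numeric(p) || p <= 0 || !is.numeric(q) || q <= 0)
    stop("p and q must be positive")
  if (r < 1 || l < 2) stop("need r >= 1 and l >= 2")
  structure(list(p = p, q = q, r = as.integer(r), l = as.integer(l),
                 weighted = isTRUE(weighted), seed = as.integer(seed)),
            class = "walk_config")
}

#' Skip-gram training configuration
#'
#' Defaults: embedding dimension `d = 128`, context window `k = 10`,
#' 5 negative samples per positive pair, 5 epochs, initial learning rate
#' 0.025 with linear decay, negatives drawn from the unigram distribution
#' raised to 0.75.
#'
#' @param d Embedding dimension (>= 1).
#' @param k Context window size (>= 1).
#' @param negative Negative samples per positive pair.
#' @param epochs Passes over the walk corpus.
#' @param initial_learning_rate Starting SGD step size.
#' @param seed Integer seed for initialisation and negative sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(d = 128, k = 10, negative = 5, epochs = 5,
                         initial_learning_rate = 0.025, seed = 1L) {
  if (d < 1 || k < 1) stop("need d >= 1 and k >= 1")
  if (negative < 1 || epochs < 1 || initial_learning_rate <= 0)
    stop("invalid training parameters")
  structure(list(d = as.integer(d), k = as.integer(k),
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Second-order transition bias
#'
#' The unnormalized probability factor for stepping from the current node to
#' a candidate, given the candidate's graph distance from the *previous*
#' node: `1/p` at distance 0 (returning), 1 at distance 1 (a common
#' neighbor), `1/q` at distance 2 (moving outward). With weighted
#' transitions the factor is multiplied by the edge weight.
#'
#' @param distance Distance from the previous node to the candidate: 0, 1
#'   or 2.
#' @param p,q Return and in-out parameters (> 0).
#' @param weight Edge weight multiplier (default 1).
#' @return Nonnegative numeric bias.
#' @export
transition_bias <- function(distance, p, q, weight = 1) {
  if (any(p <= 0) || any(q <= 0)) stop("p and q must be positive")
  if (!all(distance %in% c(0, 1, 2))) stop("distance must be 0, 1 or 2")
  base <- ifelse(distance == 0, 1 / p, ifelse(distance == 1, 1, 1 / q))
  base * weight
}

# igraph -> 0-based sorted adjacency lists + parallel weights
graph_adjacency <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- vector("list", n)
  wts <- vector("list", n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, nrow(el))
  for (i in seq_len(n)) { adj[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  if (nrow(el) > 0) {
    for (k in seq_len(nrow(el))) {
      a <- el[k, 1]; b <- el[k, 2]
      if (a == b) next
      adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
      adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
    }
    for (i in seq_len(n)) {
      ord <- order(adj[[i]])
      adj[[i]] <- as.integer(adj[[i]][ord] - 1L)
      wts[[i]] <- as.numeric(wts[[i]][ord])
    }
  }
  list(adj = adj, wts = wts)
}

#' Simulate second-order biased random walks
#'
#' Starts `r` walks from every node (start order shuffled each round under
#' the seed); each step samples the next node with probability proportional
#' to [transition_bias()] times the edge weight when weighted transitions
#' are on, using precomputed alias tables per directed (previous, current)
#' pair. Walks truncate early at nodes without neighbors, so isolated nodes
#' yield length-1 walks. Identical seeds give identical corpora.
#'
#' @param graph Undirected [igraph::igraph] (non-empty).
#' @param cfg A [walk_config()].
#' @return List of character vectors of node names (`r * vcount` walks),
#'   with the configuration attached as attribute `config`.
#' @export
simulate_walks <- function(graph, cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"))
  if (igraph::vcount(graph) == 0) stop("graph has no nodes")
  ad <- graph_adjacency(graph)
  walks <- cpp_simulate_walks(ad$adj, ad$wts, cfg$p, cfg$q, cfg$r, cfg$l,
                              cfg$weighted, as.double(cfg$seed))
  nm <- igraph::V(graph)$name
  out <- lapply(walks, function(w) nm[w + 1L])
  attr(out, "config") <- cfg
  out
}

#' Train skip-gram with negative sampling on node walks
#'
#' Every pair of nodes within `k` positions of each other in a walk forms a
#' (center, context) training pair; the skip-gram objective with `negative`
#' sampled negatives is ascended by per-pair SGD under a linearly decaying
#' learning rate. Nodes that never occur in any walk get no vector.
#'
#' @param walks List of character vectors of node names (from
#'   [simulate_walks()] or read back from disk).
#' @param cfg A [train_config()].
#' @return Numeric matrix, one row per embedded node (rownames = node
#'   names), `d` columns.
#' @export
train_skipgram <- function(walks, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(walks) == 0) stop("walk corpus is empty")
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  walks0 <- lapply(walks, function(w) unname(idx[w]))
  fit <- cpp_train_sgns(walks0, length(vocab), cfg$d, cfg$k, cfg$negative,
                        cfg$epochs, cfg$initial_learning_rate,
                        as.double(cfg$seed))
  emb <- fit$vectors
  rownames(emb) <- vocab
  emb[fit$counts > 0, , drop = FALSE]
}

#' Learn node2vec embeddings from a co-occurrence network
#'
#' Composition of [simulate_walks()] and [train_skipgram()]. The defaults
#' (`p = 1`, `q = 0.5`, `d = 128`, `r = l = 10`, `k = 10`) favor homophily:
#' nodes of the same densely connected community end up with similar
#' vectors.
#'
#' @param graph Undirected [igraph::igraph].
#' @param walk_cfg A [walk_config()].
#' @param train_cfg A [train_config()].
#' @return Embedding matrix as in [train_skipgram()].
#' @export
node2vec_embed <- function(graph, walk_cfg = walk_config(),
                           train_cfg = train_config()) {
  walks <- simulate_walks(graph, walk_cfg)
  train_skipgram(walks, train_cfg)
}

#' Learn DeepWalk embeddings (uniform-walk special case)
#'
#' DeepWalk is node2vec with both biases switched off: `p` and `q` are
#' forced to 1 so every transition is first-order. All other parameters are
#' shared with [node2vec_embed()] so the two methods are directly
#' comparable; set `weighted = FALSE` in `walk_cfg` for the classic
#' unweighted-uniform walk.
#'
#' @inheritParams node2vec_embed
#' @return Embedding matrix as in [train_skipgram()].
#' @export
deepwalk_embed <- function(graph, walk_cfg = walk_config(),
                           train_cfg = train_config()) {
  walk_cfg$p <- 1
  walk_cfg$q <- 1
  node2vec_embed(graph, walk_cfg, train_cfg)
}

#' Read / write embeddings in word2vec text format
#'
#' Header line `"n d"`, then one line per node: `name v1 ... vd`.
#'
#' @param emb Embedding matrix with rownames.
#' @param path File path.
#' @return `read_embeddings` returns the matrix; `write_embeddings` returns
#'   `path` invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  lines <- vapply(seq_len(nrow(emb)), function(i)
    paste(rownames(emb)[i],
          paste(sprintf("%.17g", emb[i, ]), collapse = " ")),
    character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- lapply(strsplit(lines[-1], "[[:space:]]+"),
                  function(p) p[nzchar(p)])
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(emb) <- vapply(parts, `[`, character(1), 1)
  emb
}

#' Write walks as plain text
#'
#' One walk per line, node names whitespace-separated.
#'
#' @param walks List of character vectors.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, character(1), collapse = " "), path)
  invisible(path)
}
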
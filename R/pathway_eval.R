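#' Construct a KEGG-style pathway model
#'
#' A pathway holds typed entities (`gene`, `disease`, `molecular_function`),
#' edges typed `direct` or `indirect` (indirect edges carry the auxiliary
#' pathway they participate in), and optional expansion chains that spell out
#' an indirect interaction as a sequence of intermediate entities taken from
#' that auxiliary pathway.
#'
#' @param entities data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `source`, `target`, `interaction`
#'   (`"direct"`/`"indirect"`), `directed` (logical), and optionally
#'   `participating_pathway` (`NA` for direct edges).
#' @param expansions List of expansion chains, each a list with elements
#'   `source`, `target` (the indirect edge expanded), `chain` (ordered ids,
#'   length >= 3, connecting the edge's endpoints in either orientation) and
#'   optionally `undirected`, a list of length-2 id vectors naming
#'   consecutive chain pairs that are undirected associations rather than
#'   directed direct links.
#' @return An object of class `pathway`.
#' @export
pathway <- function(entities, edges, expansions = list()) {
  stopifnot(all(c("id", "type") %in% names(entities)),
            all(c("source", "target", "interaction", "directed") %in%
                  names(edges)))
  if (anyDuplicated(entities$id)) stop("entity ids must be unique")
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  if (!all(edges$interaction %in% c("direct", "indirect")))
    stop("interaction must be 'direct' or 'indirect'")
  if (!"participating_pathway" %in% names(edges))
    edges$participating_pathway <- NA_character_
  for (ex in expansions) {
    if (length(ex$chain) < 3)
      stop("expansion chain must contain at least 3 nodes")
    ep <- c(ex$source, ex$target)
    ch <- c(ex$chain[1], ex$chain[length(ex$chain)])
    if (!setequal(ep, ch))
      stop("chain endpoints must be the expanded edge's endpoints: ",
           paste(ep, collapse = "-"))
  }
  structure(list(entities = entities, edges = edges,
                 expansions = expansions),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %d entities, %d edges (%d indirect), %d expansions\n",
              nrow(x$entities), nrow(x$edges),
              sum(x$edges$interaction == "indirect"), length(x$expansions)))
  invisible(x)
}

# Match an expansion to a pathway edge (either orientation); error when it
# references a direct edge or none at all.
expansion_edge_index <- function(pathway, ex) {
  e <- pathway$edges
  hit <- which((e$source == ex$source & e$target == ex$target) |
                 (e$source == ex$target & e$target == ex$source))
  if (length(hit) == 0)
    stop("expansion references a missing edge: ", ex$source, "-", ex$target)
  if (all(e$interaction[hit] == "direct"))
    stop("expansion references a direct edge: ", ex$source, "-", ex$target)
  hit[e$interaction[hit] == "indirect"][1]
}

pair_key <- function(a, b) paste(a, b, sep = "\r")
unordered_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Expand indirect interactions into direct links
#'
#' Returns the union of (a) the pathway's original direct gene-gene edges
#' and (b) the consecutive pairs of every expansion chain, excluding pairs
#' the chain marks as undirected, deduplicated as ordered pairs while
#' preserving first-seen order. Directions follow the chain order.
#'
#' @param pathway A [pathway()].
#' @param chains Expansion chains (defaults to the pathway's own).
#' @return data.frame with columns `direct_no`, `start`, `target`.
#' @export
expand_indirect_paths <- function(pathway, chains = pathway$expansions) {
  stopifnot(inherits(pathway, "pathway"))
  for (ex in chains) expansion_edge_index(pathway, ex)  # validates
  type_of <- stats::setNames(pathway$entities$type, pathway$entities$id)
  e <- pathway$edges
  is_gene <- function(id) is.na(type_of[id]) | type_of[id] == "gene"
  keep <- e$interaction == "direct" & is_gene(e$source) & is_gene(e$target)
  starts <- e$source[keep]
  targets <- e$target[keep]
  for (ex in chains) {
    und <- vapply(ex$undirected %||% list(),
                  function(pr) unordered_key(pr[1], pr[2]), character(1))
    ch <- ex$chain
    for (i in seq_len(length(ch) - 1)) {
      if (unordered_key(ch[i], ch[i + 1]) %in% und) next
      starts <- c(starts, ch[i])
      targets <- c(targets, ch[i + 1])
    }
  }
  dup <- duplicated(pair_key(starts, targets))
  out <- data.frame(start = starts[!dup], target = targets[!dup],
                    stringsAsFactors = FALSE)
  cbind(direct_no = seq_len(nrow(out)), out)
}

#' Undirected links produced by expansion chains
#'
#' The consecutive chain pairs flagged as undirected (excluded from the
#' directed evaluation set but part of the extended network).
#'
#' @param pathway A [pathway()].
#' @return data.frame with columns `a`, `b`, deduplicated as unordered pairs.
#' @export
expansion_undirected_links <- function(pathway) {
  a <- character(0); b <- character(0)
  for (ex in pathway$expansions) {
    for (pr in ex$undirected %||% list()) {
      a <- c(a, pr[1]); b <- c(b, pr[2])
    }
  }
  dup <- duplicated(unordered_key(a, b))
  data.frame(a = a[!dup], b = b[!dup], stringsAsFactors = FALSE)
}

#' Count links captured by a method
#'
#' @param records Rank-record data.frame (see [rank_table()]).
#' @param K Optional consistency check: all records must share this list
#'   size.
#' @return Number of records whose rank is not [NOT_CAPTURED].
#' @export
capture_count <- function(records, K = NULL) {
  if (!is.null(K) && !all(records$K == K))
    stop("records were computed at a different K")
  sum(!is.na(records$rank))
}

#' Count links ranked within a threshold
#'
#' @param records Rank-record data.frame.
#' @param threshold Rank threshold (>= 1).
#' @return Number of captured records with `rank <= threshold`.
#' @export
within_rank_count <- function(records, threshold) {
  if (threshold < 1) stop("threshold must be >= 1")
  sum(!is.na(records$rank) & records$rank <= threshold)
}

#' Head-to-head rank comparison of two methods
#'
#' Over the pairs captured by *both* methods: a win for `a` when its rank is
#' smaller (better), a loss when larger, a tie when equal. Pairs missed by
#' either method are excluded from the triple and reported separately.
#'
#' @param a,b Rank-record data.frames over the same (start, target) pairs.
#' @return List with `wins`, `losses`, `ties`, `n_compared`, `n_excluded`.
#' @export
head_to_head <- function(a, b) {
  key_a <- pair_key(a$start, a$target)
  key_b <- pair_key(b$start, b$target)
  if (!identical(sort(key_a), sort(key_b)))
    stop("the two methods cover different (start, target) pairs")
  b <- b[match(key_a, key_b), ]
  both <- !is.na(a$rank) & !is.na(b$rank)
  list(wins = sum(both & a$rank < b$rank),
       losses = sum(both & a$rank > b$rank),
       ties = sum(both & a$rank == b$rank),
       n_compared = sum(both),
       n_excluded = sum(!both))
}

#' Forward versus reversed ranking of directed pairs
#'
#' Computes the rank of the target in the start's top-K list and the rank of
#' the start in the target's top-K list, under the same embedding. Cosine
#' similarity is symmetric, but the competitor set changes with the starting
#' node, so a reversed pair can rank strictly worse or drop out of the list
#' entirely; an unembedded entity yields [NOT_CAPTURED] for that direction.
#'
#' @param emb Embedding matrix.
#' @param pairs data.frame with columns `start`, `target`.
#' @param K List size.
#' @param type_filter,node_types As in [top_k_similar()].
#' @return data.frame with columns `start`, `target`, `forward_rank`,
#'   `reversed_rank`, `K`.
#' @export
direction_reversal <- function(emb, pairs, K = 100, type_filter = "gene",
                               node_types = NULL) {
  fwd <- suppressWarnings(
    rank_table(emb, pairs, K, type_filter, node_types, method = "forward"))
  rev_pairs <- data.frame(start = pairs$target, target = pairs$start,
                          stringsAsFactors = FALSE)
  bwd <- suppressWarnings(
    rank_table(emb, rev_pairs, K, type_filter, node_types,
               method = "reversed"))
  data.frame(start = pairs$start, target = pairs$target,
             forward_rank = fwd$rank, reversed_rank = bwd$rank,
             K = as.integer(K), stringsAsFactors = FALSE)
}

#' Degree centrality of every node
#'
#' Raw degree (number of incident edges, direction ignored); the hub is the
#' argmax.
#'
#' @param network Undirected [igraph::igraph].
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network)
  stats::setNames(as.integer(d), igraph::V(network)$name)
}

#' Build an extended pathway network
#'
#' Node set = union of endpoints; edge set = the directed direct links plus
#' extra undirected links, deduplicated as unordered pairs.
#'
#' @param direct_links data.frame with columns `start`, `target`.
#' @param extra_undirected Optional data.frame with columns `a`, `b`.
#' @return Undirected [igraph::igraph].
#' @export
build_extended_network <- function(direct_links,
                                   extra_undirected = NULL) {
  a <- direct_links$start
  b <- direct_links$target
  if (!is.null(extra_undirected) && nrow(extra_undirected) > 0) {
    a <- c(a, extra_undirected$a)
    b <- c(b, extra_undirected$b)
  }
  if (length(a) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  keep <- !duplicated(unordered_key(a, b))
  igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Summarize method performance
#'
#' @param records_list Named list of rank-record data.frames, one per
#'   method.
#' @param threshold Rank threshold for the within-rank count (default 10).
#' @return data.frame with columns `method`, `n_links`, `captured`,
#'   `within_threshold`, `threshold`.
#' @export
evaluation_summary <- function(records_list, threshold = 10) {
  do.call(rbind, lapply(names(records_list), function(m) {
    r <- records_list[[m]]
    data.frame(method = m, n_links = nrow(r), captured = capture_count(r),
               within_threshold = within_rank_count(r, threshold),
               threshold = as.integer(threshold), stringsAsFactors = FALSE)
  }))
}
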
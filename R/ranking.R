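#' Sentinel for links a method failed to capture
#'
#' A pathway link counts as captured when the target appears in the start
#' entity's top-K candidate list; otherwise its rank is the `NOT_CAPTURED`
#' sentinel (`NA_integer_`), printed as "-" in rank tables.
#'
#' @format An integer scalar (`NA_integer_`).
#' @export
NOT_CAPTURED <- NA_integer_

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length; both must be nonzero.
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Most similar entities to a starting entity
#'
#' Candidates are all embedded nodes except `start`, optionally restricted to
#' a semantic category; the top `K` by cosine similarity are returned in
#' descending order, ties broken lexicographically by id.
#'
#' @param emb Embedding matrix (rownames = node ids).
#' @param start Starting entity id (must be embedded).
#' @param K List size (default 100).
#' @param type_filter Candidate category (default `"gene"`; `NULL` disables
#'   filtering).
#' @param node_types Named character vector mapping node ids to categories;
#'   required when `type_filter` is not `NULL`. Candidates without an entry
#'   are dropped.
#' @return data.frame with columns `entity`, `score`, ordered by descending
#'   score, at most `K` rows, with attribute `start`.
#' @export
top_k_similar <- function(emb, start, K = 100, type_filter = "gene",
                          node_types = NULL) {
  if (!start %in% rownames(emb)) stop("start entity not embedded: ", start)
  cand <- setdiff(rownames(emb), start)
  if (!is.null(type_filter)) {
    if (is.null(node_types))
      stop("node_types is required when type_filter is set")
    cand <- cand[!is.na(node_types[cand]) & node_types[cand] == type_filter]
  }
  if (length(cand) == 0)
    return(structure(data.frame(entity = character(0), score = numeric(0),
                                stringsAsFactors = FALSE), start = start))
  v <- emb[start, ]
  m <- emb[cand, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("cosine similarity undefined for zero vector")
  scores <- as.numeric(m %*% v) / (norms * sqrt(sum(v^2)))
  ord <- order(-scores, cand)
  n <- min(K, length(cand))
  structure(data.frame(entity = cand[ord][seq_len(n)],
                       score = scores[ord][seq_len(n)],
                       stringsAsFactors = FALSE),
            start = start)
}

#' Rank of a target within a similarity list
#'
#' @param sim_list data.frame from [top_k_similar()] (or any ranked list with
#'   an `entity` column).
#' @param target Entity id looked for.
#' @return 1-based rank, or [NOT_CAPTURED] when the target is absent.
#' @export
rank_of_target <- function(sim_list, target) {
  hit <- which(sim_list$entity == target)
  if (length(hit) == 0) NOT_CAPTURED else as.integer(hit[1])
}

#' Rank a set of (start, target) pairs under an embedding
#'
#' Applies [top_k_similar()] + [rank_of_target()] to every pair. Pairs whose
#' start entity is not embedded yield [NOT_CAPTURED] with a warning.
#'
#' @param emb Embedding matrix.
#' @param pairs data.frame with columns `start`, `target`.
#' @param K List size.
#' @param type_filter,node_types As in [top_k_similar()].
#' @param method Label recorded in the output (e.g. `"node2vec"`).
#' @return data.frame of rank records: `method`, `start`, `target`, `rank`
#'   (integer, `NA` = not captured), `K`.
#' @export
rank_table <- function(emb, pairs, K = 100, type_filter = "gene",
                       node_types = NULL, method = "node2vec") {
  stopifnot(all(c("start", "target") %in% names(pairs)))
  n <- nrow(pairs)
  ranks <- rep(NOT_CAPTURED, n)
  missing_start <- character(0)
  for (i in seq_len(n)) {
    s <- pairs$start[i]
    if (!s %in% rownames(emb)) {
      missing_start <- c(missing_start, s)
      next
    }
    sl <- top_k_similar(emb, s, K = K, type_filter = type_filter,
                        node_types = node_types)
    ranks[i] <- rank_of_target(sl, pairs$target[i])
  }
  if (length(missing_start) > 0)
    warning("start entities without embedding, reported as not captured: ",
            paste(unique(missing_start), collapse = ", "))
  data.frame(method = rep_len(method, n), start = pairs$start,
             target = pairs$target, rank = as.integer(ranks),
             K = rep_len(as.integer(K), n), stringsAsFactors = FALSE)
}

#' Rank pairs by the co-occurrence baseline
#'
#' Same record layout as [rank_table()], with ranks taken from
#' [cooccurrence_topk()] counts.
#'
#' @param graph Co-occurrence network.
#' @param pairs data.frame with columns `start`, `target`.
#' @param K List size.
#' @param type_filter Candidate category.
#' @return data.frame of rank records (`method = "cooccurrence"`).
#' @export
cooccurrence_rank_table <- function(graph, pairs, K = 100,
                                    type_filter = "gene") {
  n <- nrow(pairs)
  ranks <- rep(NOT_CAPTURED, n)
  nodes <- igraph::V(graph)$name
  for (i in seq_len(n)) {
    s <- pairs$start[i]
    if (!s %in% nodes) next
    tk <- cooccurrence_topk(graph, s, K = K, type_filter = type_filter)
    hit <- which(tk$entity == pairs$target[i])
    if (length(hit) > 0) ranks[i] <- tk$rank[hit[1]]
  }
  data.frame(method = rep_len("cooccurrence", n), start = pairs$start,
             target = pairs$target, rank = as.integer(ranks),
             K = rep_len(as.integer(K), n), stringsAsFactors = FALSE)
}

#' Write a rank table as TSV
#'
#' Columns `method`, `start`, `target`, `rank`, `K`, with "-" for links not
#' captured.
#'
#' @param records Rank-record data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(records, path) {
  out <- records
  out$rank <- ifelse(is.na(out$rank), "-", as.character(out$rank))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
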
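#' Split text into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter or digit, unless the period terminates
#' a known abbreviation (e.g. "i.e.", "et al.", "Fig.") or a single-letter
#' initial. Concatenating the result (with single spaces) recovers the input
#' up to boundary whitespace; empty sentences are never returned.
#'
#' @param text A character scalar.
#' @return Character vector of sentences (empty for blank input).
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  text <- gsub("\\s+", " ", trimws(text))
  abbrev <- c("i.e", "e.g", "cf", "vs", "al", "fig", "figs", "ref", "refs",
              "etc", "approx", "dr", "prof", "no", "st", "ca", "resp")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  cut_after <- integer(0)
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i == n) next
    # punctuation run: only split at its last character
    if (i < n && chars[i + 1] %in% c(".", "!", "?")) next
    if (chars[i + 1] != " ") next
    nxt <- if (i + 2 <= n) chars[i + 2] else ""
    if (!grepl("[A-Z0-9]", nxt)) next
    if (chars[i] == ".") {
      before <- substr(text, max(1, i - 12), i - 1)
      word <- sub(".*[^A-Za-z.]", "", before)
      word <- tolower(sub("\\.+$", "", word))
      if (word %in% abbrev) next
    }
    cut_after <- c(cut_after, i)
  }
  starts <- c(1, cut_after + 1)
  ends <- c(cut_after, n)
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

# Flat synonym table ordered longest-first for greedy longest-match
# resolution.
synonym_table <- function(dictionary) {
  canon <- rep(dictionary$ids, lengths(dictionary$synonyms))
  syn <- unlist(dictionary$synonyms, use.names = FALSE)
  ord <- order(-nchar(syn), syn)
  data.frame(canonical_id = canon[ord], synonym = syn[ord],
             lower = tolower(syn[ord]), len = nchar(syn[ord]),
             stringsAsFactors = FALSE)
}

# Locate every boundary-valid dictionary match in each of several sentences.
# Returns a list (one per sentence) of data.frames
# (canonical_id, surface_form, start, end), longest-match-first resolved,
# one row per canonical id per sentence.
match_mentions_bulk <- function(sentences, dictionary) {
  tab <- synonym_table(dictionary)
  low <- tolower(sentences)
  n <- length(sentences)
  cand_sent <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    hits <- gregexpr(tab$lower[k], low, fixed = TRUE)
    cand_sent[[k]] <- hits
  }
  out <- vector("list", n)
  for (si in seq_len(n)) {
    s <- sentences[si]
    nc <- nchar(s)
    claimed <- rep(FALSE, nc)
    rows_id <- character(0); rows_surf <- character(0)
    rows_start <- integer(0); rows_end <- integer(0)
    seen <- character(0)
    for (k in seq_len(nrow(tab))) {        # table is longest-first
      pos <- cand_sent[[k]][[si]]
      if (pos[1] == -1L) next
      len <- tab$len[k]
      for (p in as.integer(pos)) {
        e <- p + len - 1L
        # token boundaries: neighbors must be non-alphanumeric
        if (p > 1 && grepl("[[:alnum:]]", substr(s, p - 1, p - 1))) next
        if (e < nc && grepl("[[:alnum:]]", substr(s, e + 1, e + 1))) next
        if (any(claimed[p:e])) next        # overlaps a longer match
        claimed[p:e] <- TRUE
        if (tab$canonical_id[k] %in% seen) next
        seen <- c(seen, tab$canonical_id[k])
        rows_id <- c(rows_id, tab$canonical_id[k])
        rows_surf <- c(rows_surf, substr(s, p, e))
        rows_start <- c(rows_start, p)
        rows_end <- c(rows_end, e)
      }
    }
    ord <- order(rows_start)
    out[[si]] <- data.frame(canonical_id = rows_id[ord],
                            surface_form = rows_surf[ord],
                            start = rows_start[ord], end = rows_end[ord],
                            stringsAsFactors = FALSE)
  }
  out
}

#' Extract canonical gene mentions from one sentence
#'
#' Case-insensitive dictionary matching at token boundaries (a match may not
#' be flanked by alphanumeric characters; hyphens inside synonyms are
#' literal). Overlapping candidates are resolved longest-match-first, and
#' each canonical identifier is reported at most once per sentence.
#'
#' @param sentence A character scalar.
#' @param dictionary A [gene_dictionary()].
#' @return data.frame with columns `canonical_id`, `surface_form`, `start`,
#'   `end` (character offsets), ordered by position.
#' @export
extract_mentions <- function(sentence, dictionary) {
  stopifnot(inherits(dictionary, "gene_dictionary"), length(sentence) == 1)
  match_mentions_bulk(sentence, dictionary)[[1]]
}

#' Build the sentence-level co-occurrence network
#'
#' Two entities are linked whenever they are mentioned together in the same
#' sentence; the edge weight is the number of such sentences across the whole
#' corpus. Entities co-mentioned only in different sentences of one abstract
#' share no edge. The title is treated as sentence 0 of each record when
#' `include_titles` is on.
#'
#' @param records data.frame with columns `pmid`, `title`, `abstract`.
#' @param dictionary A [gene_dictionary()].
#' @param include_titles Count title mentions (default `TRUE`).
#' @return An undirected [igraph::igraph] whose vertices carry
#'   `semantic_type` and `category` attributes and whose edges carry integer
#'   `weight`s; vertices are every entity mentioned at least once.
#' @export
build_cooccurrence_graph <- function(records, dictionary,
                                     include_titles = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("pmid", "title", "abstract") %in% names(records)))
  texts <- character(0)
  if (nrow(records) > 0) {
    sent_list <- lapply(seq_len(nrow(records)), function(i) {
      s <- split_sentences(records$abstract[i])
      if (include_titles) c(records$title[i], s) else s
    })
    texts <- unlist(sent_list, use.names = FALSE)
  }
  mentioned <- character(0)
  pair_count <- new.env(parent = emptyenv())
  if (length(texts) > 0) {
    ments <- match_mentions_bulk(texts, dictionary)
    for (m in ments) {
      ids <- m$canonical_id
      if (length(ids) == 0) next
      mentioned <- union(mentioned, ids)
      if (length(ids) >= 2) {
        prs <- combn(sort(ids), 2)
        for (j in seq_len(ncol(prs))) {
          key <- paste(prs[1, j], prs[2, j], sep = "\r")
          pair_count[[key]] <- (pair_count[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  keys <- ls(pair_count)
  if (length(keys) > 0) {
    sp <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(sp, `[`, character(1), 1),
                        to = vapply(sp, `[`, character(1), 2),
                        weight = vapply(keys, function(k)
                          as.integer(pair_count[[k]]), integer(1)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }
  verts <- data.frame(name = sort(mentioned), stringsAsFactors = FALSE)
  verts$semantic_type <- unname(dictionary$types[verts$name])
  verts$category <- semantic_category(verts$semantic_type)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank a gene's co-occurrence partners
#'
#' The co-occurrence baseline: neighbors of `start` ranked by descending
#' co-mention count (1-based ranks, lexicographic tie-break on the canonical
#' id), restricted to a semantic category.
#'
#' @param graph Co-occurrence network from [build_cooccurrence_graph()].
#' @param start Canonical id of the starting entity.
#' @param K Maximum list length (default 100).
#' @param type_filter Candidate category (`"gene"`, another category label,
#'   or `NULL` for no filter).
#' @return data.frame with columns `entity`, `weight`, `rank`.
#' @export
cooccurrence_topk <- function(graph, start, K = 100, type_filter = "gene") {
  if (!start %in% igraph::V(graph)$name)
    stop("start entity not in graph: ", start)
  inc <- igraph::incident(graph, start)
  if (length(inc) == 0)
    return(data.frame(entity = character(0), weight = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  ends <- igraph::ends(graph, inc)
  other <- ifelse(ends[, 1] == start, ends[, 2], ends[, 1])
  w <- igraph::edge_attr(graph, "weight", inc)
  if (!is.null(type_filter)) {
    cat_map <- stats::setNames(igraph::V(graph)$category,
                               igraph::V(graph)$name)
    keep <- cat_map[other] == type_filter
    other <- other[keep]; w <- w[keep]
  }
  ord <- order(-w, other)
  other <- other[ord]; w <- w[ord]
  n <- min(K, length(other))
  data.frame(entity = other[seq_len(n)], weight = w[seq_len(n)],
             rank = seq_len(n), stringsAsFactors = FALSE)
}
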
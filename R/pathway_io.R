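#' Read / write a pathway as JSON
#'
#' Schema: `entities: [{id, type}]`, `edges: [{source, target, interaction,
#' directed, participating_pathway}]`, `expansions: [{source, target,
#' chain: [ids], undirected: [[a, b], ...]}]`.
#'
#' @param path File path.
#' @return `read_pathway_json` returns a [pathway()]; `write_pathway_json`
#'   returns `path` invisibly.
#' @export
read_pathway_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                          simplifyMatrix = FALSE)
  expansions <- normalize_expansions(x$expansions %||% list())
  edges <- x$edges
  if (!"participating_pathway" %in% names(edges))
    edges$participating_pathway <- NA_character_
  pathway(x$entities, edges, expansions)
}

#' @rdname read_pathway_json
#' @param pw A [pathway()].
#' @export
write_pathway_json <- function(pw, path) {
  stopifnot(inherits(pw, "pathway"))
  x <- list(entities = pw$entities, edges = pw$edges,
            expansions = lapply(pw$expansions, function(ex)
              list(source = jsonlite::unbox(ex$source),
                   target = jsonlite::unbox(ex$target),
                   chain = ex$chain,
                   undirected = ex$undirected %||% list())))
  jsonlite::write_json(x, path, na = "null", null = "list", pretty = TRUE)
  invisible(path)
}

# jsonlite returns expansions as a data.frame when read with
# simplifyDataFrame = TRUE; normalize to a list of lists.
#' @noRd
normalize_expansions <- function(ex) {
  if (is.data.frame(ex)) {
    lapply(seq_len(nrow(ex)), function(i)
      list(source = ex$source[i], target = ex$target[i],
           chain = unlist(ex$chain[[i]]),
           undirected = lapply(ex$undirected[[i]] %||% list(), unlist)))
  } else {
    lapply(ex, function(e)
      list(source = e$source, target = e$target, chain = unlist(e$chain),
           undirected = lapply(e$undirected %||% list(), unlist)))
  }
}

#' Load the encoded type 2 diabetes pathway tables
#'
#' Ships, hand-encoded from the insulin-resistance-focused slice of the KEGG
#' type 2 diabetes mellitus pathway: the 19 entities, the 18 gene-gene
#' interactions (9 of them indirect, each with its auxiliary pathway), the
#' expansion chains that turn the 9 indirect interactions into chains of
#' direct links, and the published per-method rankings of the resulting 30
#' direct links at K = 100. Entity labels are normalized (IRS1/IRS, TNFA,
#' PKCZ, ERK1/2 for merged or renamed forms).
#'
#' @return List with elements `pathway` (a [pathway()]), `expansions` (its
#'   chains), `rank_table` (data.frame `direct_no`, `start`, `target`,
#'   `node2vec`, `cooccurrence`, `deepwalk`; `NA` = not captured) and
#'   `extra_undirected` (the five undirected links used only in the extended
#'   network).
#' @export
load_t2d_fixture <- function() {
  pw_path <- system.file("extdata", "t2d_pathway.json", package = "litpath",
                         mustWork = TRUE)
  rk_path <- system.file("extdata", "t2d_rank_table.tsv", package = "litpath",
                         mustWork = TRUE)
  pw <- read_pathway_json(pw_path)
  list(pathway = pw,
       expansions = pw$expansions,
       rank_table = read_t2d_rank_table(rk_path),
       extra_undirected = expansion_undirected_links(pw))
}

#' Read a published rank table
#'
#' TSV with columns `direct_no`, `start`, `target` and one integer-or-dash
#' column per method ("-" = not captured).
#'
#' @param path File path.
#' @return data.frame with method columns as integers (`NA` = not captured).
#' @export
read_t2d_rank_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("direct_no", "start", "target")
  if (!all(need %in% names(df)))
    stop("rank table must have columns: ", paste(need, collapse = ", "))
  df$direct_no <- as.integer(df$direct_no)
  for (col in setdiff(names(df), need)) {
    raw <- df[[col]]
    bad <- which(raw != "-" & !grepl("^[0-9]+$", raw))
    if (length(bad) > 0)
      stop(sprintf("malformed rank '%s' in column '%s' at row %d of %s",
                   raw[bad[1]], col, bad[1], path))
    val <- rep(NA_integer_, length(raw))
    val[raw != "-"] <- as.integer(raw[raw != "-"])
    df[[col]] <- val
  }
  df
}

#' Rank records for one method of a published rank table
#'
#' @param tbl Table from [read_t2d_rank_table()] / [load_t2d_fixture()].
#' @param method Method column name (e.g. `"node2vec"`).
#' @param K List size the published ranks used (default 100).
#' @return Rank-record data.frame as produced by [rank_table()].
#' @export
t2d_rank_records <- function(tbl, method, K = 100) {
  if (!method %in% names(tbl)) stop("no such method column: ", method)
  data.frame(method = method, start = tbl$start, target = tbl$target,
             rank = as.integer(tbl[[method]]), K = as.integer(K),
             stringsAsFactors = FALSE)
}
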
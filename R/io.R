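#' Read PubMed-style XML records
#'
#' Extracts PMID, ArticleTitle and AbstractText from `PubmedArticle`
#' records; multi-paragraph abstracts are concatenated with a space.
#' Records lacking an abstract are skipped (a message reports the count).
#' With `query` set, only records whose title or abstract contains the
#' phrase (case-insensitive) are kept, mirroring a keyword-restricted
#' download.
#'
#' @param path XML file path.
#' @param query Optional filter phrase.
#' @return data.frame with columns `pmid`, `title`, `abstract` and
#'   attribute `n_skipped`.
#' @export
read_pubmed_xml <- function(path, query = NULL) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  pmid <- character(0); title <- character(0); abstract <- character(0)
  skipped <- 0L
  for (a in arts) {
    abst <- xml2::xml_find_all(a, ".//AbstractText")
    if (length(abst) == 0) {
      skipped <- skipped + 1L
      next
    }
    pmid <- c(pmid, xml2::xml_text(xml2::xml_find_first(a, ".//PMID")))
    title <- c(title,
               xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle")))
    abstract <- c(abstract, paste(trimws(xml2::xml_text(abst)),
                                  collapse = " "))
  }
  if (skipped > 0)
    message(skipped, " record(s) without an abstract were skipped")
  out <- data.frame(pmid = pmid, title = title, abstract = abstract,
                    stringsAsFactors = FALSE)
  if (!is.null(query) && nrow(out) > 0) {
    keep <- grepl(query, paste(out$title, out$abstract), ignore.case = TRUE,
                  fixed = FALSE)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write a corpus as PubMed-style XML
#'
#' One `PubmedArticle` per record with `PMID`, `ArticleTitle` and
#' `AbstractText` elements, round-trippable through [read_pubmed_xml()].
#'
#' @param records data.frame with columns `pmid`, `title`, `abstract`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pubmed_xml <- function(records, path) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$pmid[i])
    ar <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(ar, "ArticleTitle", records$title[i])
    ab <- xml2::xml_add_child(ar, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", records$abstract[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write a corpus as TSV
#'
#' Columns `pmid`, `title`, `abstract`.
#'
#' @param records data.frame of abstract records.
#' @param path File path.
#' @return `read_corpus_tsv` returns the data.frame; `write_corpus_tsv`
#'   returns `path` invisibly.
#' @export
write_corpus_tsv <- function(records, path) {
  write.table(records[, c("pmid", "title", "abstract")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character", quote = "")
}

#' Read / write a weighted co-occurrence graph as edge-list TSV
#'
#' Columns `node_a`, `node_b`, `weight`. Semantic types are restored from
#' the dictionary when one is supplied.
#'
#' @param graph Undirected weighted [igraph::igraph].
#' @param path File path.
#' @param dictionary Optional [gene_dictionary()] for vertex types.
#' @return `read_edgelist_tsv` returns the graph; `write_edgelist_tsv`
#'   returns `path` invisibly.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   weight = igraph::E(graph)$weight,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path, dictionary = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(df)))
  verts <- data.frame(name = sort(unique(c(df$node_a, df$node_b))),
                      stringsAsFactors = FALSE)
  if (!is.null(dictionary)) {
    verts$semantic_type <- unname(dictionary$types[verts$name])
    verts$category <- semantic_category(verts$semantic_type)
  }
  igraph::graph_from_data_frame(
    data.frame(from = df$node_a, to = df$node_b, weight = df$weight,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Write a graph as GraphML
#'
#' @param graph An [igraph::igraph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Run the whole pipeline on an abstract corpus
#'
#' Chains the stages: build the sentence-level co-occurrence network, learn
#' node2vec and/or DeepWalk embeddings, rank each (start, target) pair by
#' every requested method, and summarize captures. Candidate pools are
#' restricted to gene-typed entities.
#'
#' @param records Abstract corpus (columns `pmid`, `title`, `abstract`).
#' @param dictionary A [gene_dictionary()].
#' @param pairs data.frame with columns `start`, `target` to evaluate.
#' @param walk_cfg,train_cfg Walk and training configurations; the DeepWalk
#'   run shares them with `p = q = 1` forced.
#' @param K Candidate list size.
#' @param threshold Rank threshold for the summary.
#' @param methods Subset of `c("node2vec", "deepwalk", "cooccurrence")`.
#' @return List with `graph`, `embeddings` (per embedding method),
#'   `rank_tables` (per method), and `summary`.
#' @export
run_pipeline <- function(records, dictionary, pairs,
                         walk_cfg = walk_config(),
                         train_cfg = train_config(),
                         K = 100, threshold = 10,
                         methods = c("node2vec", "deepwalk",
                                     "cooccurrence")) {
  methods <- match.arg(methods, several.ok = TRUE)
  graph <- build_cooccurrence_graph(records, dictionary)
  node_types <- stats::setNames(igraph::V(graph)$category,
                                igraph::V(graph)$name)
  embeddings <- list()
  tables <- list()
  for (m in methods) {
    if (m == "cooccurrence") {
      tables[[m]] <- cooccurrence_rank_table(graph, pairs, K = K)
    } else {
      emb <- if (m == "node2vec")
        node2vec_embed(graph, walk_cfg, train_cfg)
      else deepwalk_embed(graph, walk_cfg, train_cfg)
      embeddings[[m]] <- emb
      tables[[m]] <- suppressWarnings(
        rank_table(emb, pairs, K = K, node_types = node_types, method = m))
    }
  }
  list(graph = graph, embeddings = embeddings, rank_tables = tables,
       summary = evaluation_summary(tables, threshold = threshold))
}
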
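#' Define a planted ground-truth gene network
#'
#' The generator plants this network in a synthetic abstract corpus: each
#' true edge receives Poisson-distributed sentence co-mentions, non-edges
#' receive background noise co-mentions, and two failure modes of real
#' literature mining are representable. `absent_pairs` are true edges that
#' never co-occur in any sentence; `hidden_genes` never occur in the corpus
#' at all (the "appears only in full text" phenomenon), so all their
#' incident edges are automatically flagged absent and they are excluded
#' from noise pairs and singleton mentions.
#'
#' @param genes Character vector of canonical gene identifiers.
#' @param edges data.frame with columns `start`, `target`: the ground-truth
#'   direct links (no self-edges, endpoints in `genes`).
#' @param absent_pairs Optional data.frame with columns `start`, `target`;
#'   must be a subset of `edges`.
#' @param hidden_genes Optional character vector, subset of `genes`.
#' @return An object of class `planted_network`.
#' @export
planted_network <- function(genes, edges,
                            absent_pairs = NULL,
                            hidden_genes = character(0)) {
  genes <- as.character(genes)
  stopifnot(all(c("start", "target") %in% names(edges)))
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (any(edges$start == edges$target)) stop("self-edges are not allowed")
  if (!all(c(edges$start, edges$target) %in% genes))
    stop("every edge endpoint must be a listed gene")
  if (anyDuplicated(unordered_key(edges$start, edges$target)))
    stop("duplicate edges")
  if (!all(hidden_genes %in% genes))
    stop("hidden_genes must be a subset of genes")
  edge_keys <- unordered_key(edges$start, edges$target)
  if (is.null(absent_pairs))
    absent_pairs <- data.frame(start = character(0), target = character(0),
                               stringsAsFactors = FALSE)
  if (!all(unordered_key(absent_pairs$start, absent_pairs$target) %in%
             edge_keys))
    stop("absent_pairs must be a subset of edges")
  # edges touching a hidden gene can never be co-mentioned
  hid <- edges$start %in% hidden_genes | edges$target %in% hidden_genes
  add <- hid & !(edge_keys %in%
                   unordered_key(absent_pairs$start, absent_pairs$target))
  absent_pairs <- rbind(absent_pairs,
                        edges[add, c("start", "target")])
  rownames(absent_pairs) <- NULL
  structure(list(genes = genes,
                 edges = edges[, c("start", "target")],
                 absent_pairs = absent_pairs,
                 hidden_genes = hidden_genes),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf(
    "<planted_network> %d genes, %d edges (%d absent), %d hidden genes\n",
    length(x$genes), nrow(x$edges), nrow(x$absent_pairs),
    length(x$hidden_genes)))
  invisible(x)
}

#' Planted-partition (stochastic block) ground-truth network
#'
#' The default study conditions of this package's analyses: 30 genes in 3
#' equal blocks, within-block edge probability 0.5, between-block 0.05, and
#' 2 hidden genes (drawn among genes with at least one edge) whose incident
#' edges become the absent pairs.
#'
#' @param n_genes Number of genes.
#' @param n_blocks Number of equal-sized communities.
#' @param p_within,p_between Edge probabilities inside / across blocks.
#' @param n_hidden Number of hidden (full-text-only) genes.
#' @param seed Integer seed.
#' @return A [planted_network()] with a `block` attribute (named integer
#'   vector of community labels).
#' @export
planted_block_network <- function(n_genes = 30, n_blocks = 3,
                                  p_within = 0.5, p_between = 0.05,
                                  n_hidden = 2, seed = 1L) {
  stopifnot(n_genes >= n_blocks, p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1, n_hidden >= 0)
  genes <- sprintf("G%02d", seq_len(n_genes))
  block <- stats::setNames(sort(rep(seq_len(n_blocks),
                                    length.out = n_genes)), genes)
  with_local_seed(seed, {
    starts <- character(0); targets <- character(0)
    for (i in seq_len(n_genes - 1)) {
      for (j in (i + 1):n_genes) {
        pr <- if (block[i] == block[j]) p_within else p_between
        if (runif(1) < pr) {
          starts <- c(starts, genes[i]); targets <- c(targets, genes[j])
        }
      }
    }
    edges <- data.frame(start = starts, target = targets,
                        stringsAsFactors = FALSE)
    with_edge <- unique(c(edges$start, edges$target))
    hidden <- character(0)
    if (n_hidden > 0 && length(with_edge) > 0)
      hidden <- sort(sample(with_edge, min(n_hidden, length(with_edge))))
    net <- planted_network(genes, edges, hidden_genes = hidden)
    attr(net, "block") <- block
    net
  })
}

#' Synthetic corpus configuration
#'
#' Defaults are the package's study conditions: 2,000 abstracts of 8
#' sentences, an expected 50 sentence co-mentions per true edge over the
#' whole corpus, 0.5 per background (non-edge) pair, a 0.2 probability of
#' writing a synonym instead of the primary surface form, and singleton
#' gene mentions in 30% of filler sentences.
#'
#' @param n_abstracts Number of abstracts.
#' @param sentences_per_abstract Sentences per abstract: a count or a
#'   length-2 inclusive range.
#' @param lambda_direct Expected co-mentions per non-absent true edge per
#'   corpus (> 0).
#' @param lambda_noise Expected co-mentions per visible non-edge pair per
#'   corpus (>= 0).
#' @param synonym_usage_prob Probability, per mention, of emitting an
#'   alternative synonym rather than the primary surface form.
#' @param singleton_prob Probability that a filler sentence carries one
#'   gene mention.
#' @param title_mentions Put a gene mention in each title (default off;
#'   titles are still scanned by the miner either way).
#' @param seed Integer seed.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_abstracts = 2000, sentences_per_abstract = 8,
                          lambda_direct = 50, lambda_noise = 0.5,
                          synonym_usage_prob = 0.2, singleton_prob = 0.3,
                          title_mentions = FALSE, seed = 1L) {
  if (n_abstracts < 1) stop("n_abstracts must be positive")
  if (!length(sentences_per_abstract) %in% c(1, 2) ||
        any(sentences_per_abstract < 1))
    stop("sentences_per_abstract must be a positive count or range")
  if (lambda_direct <= 0) stop("lambda_direct must be positive")
  if (lambda_noise < 0) stop("lambda_noise must be nonnegative")
  for (pr in c(synonym_usage_prob, singleton_prob))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  structure(list(n_abstracts = as.integer(n_abstracts),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 lambda_direct = lambda_direct, lambda_noise = lambda_noise,
                 synonym_usage_prob = synonym_usage_prob,
                 singleton_prob = singleton_prob,
                 title_mentions = isTRUE(title_mentions),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Dictionary for a set of synthetic genes
#'
#' Each gene gets its identifier as primary surface form plus a multi-word
#' alternative synonym ("<id> protein"), exercising canonicalization and
#' longest-match resolution downstream.
#'
#' @param genes Character vector of gene identifiers.
#' @return A [gene_dictionary()].
#' @export
synthetic_gene_dictionary <- function(genes) {
  gene_dictionary(genes,
                  synonyms = lapply(genes, function(g)
                    c(g, paste(g, "protein"))),
                  types = "Gene or Genome")
}

pair_sentence_templates <- c(
  "%s interacts with %s in pancreatic beta cells.",
  "Expression of %s was strongly correlated with %s in diabetic patients.",
  "%s signaling modulates %s activity under chronic hyperglycemia.",
  "Knockdown of %s markedly reduced %s phosphorylation in cultured myotubes.")

singleton_sentence_templates <- c(
  "%s expression increased after eight weeks of treatment.",
  "Circulating levels of %s were elevated in the obese cohort.",
  "%s was profiled by quantitative PCR across all biopsies.")

filler_sentence_templates <- c(
  "Glucose tolerance was assessed by standardized oral testing.",
  "Participants were followed for an average of five years.",
  "Insulin sensitivity declined progressively with age in this cohort.",
  "Dietary intervention improved glycemic control in most subjects.")

#' Generate a synthetic PubMed-style abstract corpus
#'
#' Sentence-level gene co-mentions are planted according to the network: for
#' every unordered gene pair, the number of sentences containing both genes
#' is Poisson with mean `lambda_direct` (non-absent true edges),
#' `lambda_noise` (visible non-edges), or exactly 0 (absent pairs and any
#' pair involving a hidden gene). Each co-mention event lands in a uniformly
#' chosen free sentence slot, so a sentence carries at most one planted
#' pair; remaining slots become filler sentences, some with singleton
#' mentions of visible genes. Identical seeds give identical corpora.
#'
#' @param network A [planted_network()].
#' @param config A [corpus_config()].
#' @param dictionary A [gene_dictionary()] covering every network gene.
#' @return data.frame with columns `pmid`, `title`, `abstract`.
#' @export
generate_corpus <- function(network, config, dictionary) {
  stopifnot(inherits(network, "planted_network"),
            inherits(config, "corpus_config"),
            inherits(dictionary, "gene_dictionary"))
  missing <- setdiff(network$genes, dictionary$ids)
  if (length(missing) > 0)
    stop("genes without a dictionary entry: ",
         paste(missing, collapse = ", "))

  visible <- setdiff(network$genes, network$hidden_genes)
  absent_keys <- unordered_key(network$absent_pairs$start,
                               network$absent_pairs$target)
  edge_keys <- unordered_key(network$edges$start, network$edges$target)
  live <- !(edge_keys %in% absent_keys)
  pair_a <- network$edges$start[live]
  pair_b <- network$edges$target[live]
  lambda <- rep(config$lambda_direct, sum(live))
  if (config$lambda_noise > 0 && length(visible) >= 2) {
    cmb <- combn(sort(visible), 2)
    noise_keys <- unordered_key(cmb[1, ], cmb[2, ])
    keep <- !(noise_keys %in% edge_keys)
    pair_a <- c(pair_a, cmb[1, keep])
    pair_b <- c(pair_b, cmb[2, keep])
    lambda <- c(lambda, rep(config$lambda_noise, sum(keep)))
  }

  with_local_seed(config$seed, {
    spa <- config$sentences_per_abstract
    n_sent <- if (length(spa) == 2)
      sample(spa[1]:spa[2], config$n_abstracts, replace = TRUE)
    else rep(spa, config$n_abstracts)
    total_slots <- sum(n_sent)
    counts <- rpois(length(lambda), lambda)
    n_events <- sum(counts)
    if (n_events > total_slots)
      stop("corpus too small for the requested co-mention rates: ",
           n_events, " events but only ", total_slots, " sentence slots")

    surface <- function(ids) {
      vapply(ids, function(id) {
        syns <- dictionary$synonyms[[id]]
        if (length(syns) > 1 && runif(1) < config$synonym_usage_prob)
          sample(syns[-1], 1)
        else syns[1]
      }, character(1))
    }

    slot_text <- rep(NA_character_, total_slots)
    if (n_events > 0) {
      ev_pair <- rep(seq_along(counts), counts)
      ev_slot <- sample(total_slots, n_events)
      tpl <- sample(pair_sentence_templates, n_events, replace = TRUE)
      slot_text[ev_slot] <- sprintf(tpl, surface(pair_a[ev_pair]),
                                    surface(pair_b[ev_pair]))
    }
    free <- which(is.na(slot_text))
    if (length(free) > 0 && config$singleton_prob > 0 &&
          length(visible) > 0) {
      single <- free[runif(length(free)) < config$singleton_prob]
      if (length(single) > 0) {
        tpl <- sample(singleton_sentence_templates, length(single),
                      replace = TRUE)
        slot_text[single] <-
          sprintf(tpl, surface(sample(visible, length(single),
                                      replace = TRUE)))
      }
    }
    still <- which(is.na(slot_text))
    slot_text[still] <- sample(filler_sentence_templates, length(still),
                               replace = TRUE)

    abstract_id <- rep(seq_len(config$n_abstracts), n_sent)
    abstracts <- vapply(split(slot_text, abstract_id), paste, character(1),
                        collapse = " ")
    titles <- if (config$title_mentions && length(visible) > 0)
      sprintf("Role of %s in type 2 diabetes (report %d)",
              surface(sample(visible, config$n_abstracts, replace = TRUE)),
              seq_len(config$n_abstracts))
    else sprintf("A cohort study of metabolic signaling (report %d)",
                 seq_len(config$n_abstracts))
    data.frame(pmid = sprintf("SYN%05d", seq_len(config$n_abstracts)),
               title = titles, abstract = unname(abstracts),
               stringsAsFactors = FALSE)
  })
}

#' Ground-truth pathway matching a planted network
#'
#' Every planted edge becomes a direct, directed gene-gene pathway edge, so
#' evaluation code can score rankings against the generator's truth.
#'
#' @param network A [planted_network()].
#' @return A [pathway()] with no expansions.
#' @export
planted_truth_pathway <- function(network) {
  stopifnot(inherits(network, "planted_network"))
  n <- nrow(network$edges)
  edges <- data.frame(source = network$edges$start,
                      target = network$edges$target,
                      interaction = rep_len("direct", n),
                      directed = rep_len(TRUE, n),
                      participating_pathway = rep_len(NA_character_, n),
                      stringsAsFactors = FALSE)
  pathway(data.frame(id = network$genes, type = "gene",
                     stringsAsFactors = FALSE),
          edges)
}

#' Evaluation pairs of a planted network
#'
#' @param network A [planted_network()].
#' @return data.frame with columns `start`, `target`, `absent` (flag: the
#'   pair was suppressed from the corpus).
#' @export
planted_pairs <- function(network) {
  key <- unordered_key(network$edges$start, network$edges$target)
  absent <- key %in% unordered_key(network$absent_pairs$start,
                                   network$absent_pairs$target)
  data.frame(start = network$edges$start, target = network$edges$target,
             absent = absent, stringsAsFactors = FALSE)
}

#' Write a planted network as an edge-list TSV
#'
#' Columns `start`, `target`, `absent`.
#'
#' @param network A [planted_network()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  write.table(planted_pairs(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
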
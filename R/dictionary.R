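#' UMLS-style semantic types treated as gene/protein-like
#'
#' Entity types used to restrict extraction and candidate ranking to
#' gene/protein-like concepts: Cell Component, Gene or Genome, Enzyme,
#' Receptor, Nucleic Acid Nucleoside or Nucleotide, Amino Acid Peptide or
#' Protein, Molecular Sequence, Nucleotide Sequence, and Amino Acid Sequence.
#'
#' @return Character vector of semantic type labels.
#' @export
gene_semantic_types <- function() {
  c("Cell Component", "Gene or Genome", "Enzyme", "Receptor",
    "Nucleic Acid, Nucleoside, or Nucleotide",
    "Amino Acid, Peptide, or Protein", "Molecular Sequence",
    "Nucleotide Sequence", "Amino Acid Sequence")
}

#' Does a semantic type denote a gene/protein-like entity?
#'
#' @param type Character vector of semantic type labels.
#' @return Logical vector.
#' @export
is_gene_type <- function(type) type %in% gene_semantic_types()

#' Build a gene dictionary
#'
#' A dictionary maps canonical entity identifiers to synonym lists and a
#' semantic type. Matching is case-insensitive at token boundaries; the
#' canonical identifier itself is *not* matched unless it is listed among the
#' synonyms (merged labels such as `IRS1/IRS` never occur verbatim in text).
#'
#' @param ids Character vector of unique canonical identifiers.
#' @param synonyms List of character vectors, one per id (non-empty surface
#'   forms). A single character vector is recycled element-wise. Defaults to
#'   the ids themselves.
#' @param types Character vector of semantic types (recycled).
#' @return An object of class `gene_dictionary`.
#' @export
gene_dictionary <- function(ids, synonyms = NULL, types = "Gene or Genome") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("canonical identifiers must be unique")
  if (length(ids) == 0) stop("dictionary must have at least one entry")
  if (is.null(synonyms)) synonyms <- as.list(ids)
  if (is.character(synonyms)) synonyms <- as.list(synonyms)
  if (length(synonyms) != length(ids))
    stop("synonyms must be a list with one element per id")
  synonyms <- lapply(synonyms, as.character)
  if (any(vapply(synonyms, function(s) length(s) == 0 || any(!nzchar(s)),
                 logical(1))))
    stop("every entry needs at least one non-empty synonym")
  types <- rep_len(as.character(types), length(ids))
  structure(list(ids = ids,
                 synonyms = stats::setNames(synonyms, ids),
                 types = stats::setNames(types, ids)),
            class = "gene_dictionary")
}

#' @export
print.gene_dictionary <- function(x, ...) {
  cat(sprintf("<gene_dictionary> %d entries, %d synonyms\n",
              length(x$ids), sum(lengths(x$synonyms))))
  invisible(x)
}

#' @export
length.gene_dictionary <- function(x) length(x$ids)

#' Read / write a dictionary as TSV
#'
#' Columns: `canonical_id`, `semantic_type`, `synonyms` (pipe-separated).
#'
#' @param path File path.
#' @return `read_dictionary_tsv` returns a [gene_dictionary()];
#'   `write_dictionary_tsv` returns `path` invisibly.
#' @export
read_dictionary_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("canonical_id", "semantic_type", "synonyms")
  if (!all(need %in% names(df)))
    stop("dictionary TSV must have columns: ", paste(need, collapse = ", "))
  gene_dictionary(df$canonical_id,
                  synonyms = strsplit(df$synonyms, "|", fixed = TRUE),
                  types = df$semantic_type)
}

#' @rdname read_dictionary_tsv
#' @param dictionary A [gene_dictionary()].
#' @export
write_dictionary_tsv <- function(dictionary, path) {
  df <- data.frame(canonical_id = dictionary$ids,
                   semantic_type = unname(dictionary$types),
                   synonyms = vapply(dictionary$synonyms, paste,
                                     character(1), collapse = "|"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Entity type categories used in pathway models
#'
#' Maps a dictionary semantic type onto the coarse pathway categories
#' `gene`, `disease`, `molecular_function`.
#'
#' @param types Character vector of semantic type labels.
#' @return Character vector of categories (`"other"` when unrecognized).
#' @export
semantic_category <- function(types) {
  out <- rep("other", length(types))
  out[is_gene_type(types)] <- "gene"
  out[types %in% c("Disease or Syndrome", "Disease")] <- "disease"
  out[types %in% c("Molecular Function", "Physiologic Function")] <-
    "molecular_function"
  out
}
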
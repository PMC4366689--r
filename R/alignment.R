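#' Labeled alignment of equal-length nucleotide sequences
#'
#' A `labeled_alignment` is the package's central container: a set of
#' equal-length nucleotide sequences, each tagged with a species (population)
#' label or with the reserved label `"QUERY"` for sequences under
#' identification. Internally it is a character matrix (one row per sequence,
#' one column per alignment site) of single upper-case characters, with `U`
#' normalised to `T`. Characters outside `{A,C,G,T}` (gaps, `N`, IUPAC
#' ambiguity codes) are retained verbatim but treated as missing data by all
#' downstream statistics.
#'
#' @param sequences character vector of sequence strings, all the same length,
#'   or a character matrix of single characters (one row per sequence).
#' @param ids character vector of sequence identifiers (made unique if not).
#' @param species character vector of species labels, `"QUERY"` for query
#'   sequences.
#' @return An object of class `labeled_alignment`: a list with elements
#'   `seq` (character matrix), `ids`, and `species`.
#' @examples
#' aln <- labeled_alignment(c("ACGT", "ACGA"), c("s1", "s2"),
#'                          c("Species A", "Species A"))
#' aln
#' @export
labeled_alignment <- function(sequences, ids = NULL, species = NULL) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (!is.character(sequences) || length(sequences) == 0L)
      stop("'sequences' must be a non-empty character vector or matrix")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have equal length (got lengths ",
           paste(sort(unique(lens)), collapse = ", "), ")")
    if (lens[1L] == 0L) stop("sequences must be non-empty")
    m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  }
  dimnames(m) <- NULL
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  n <- nrow(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (is.null(species)) species <- rep("QUERY", n)
  ids <- make.unique(as.character(ids), sep = "_")
  species <- as.character(species)
  if (length(ids) != n || length(species) != n)
    stop("'ids' and 'species' must match the number of sequences")
  structure(list(seq = m, ids = ids, species = species),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  tab <- table(x$species)
  cat("Labeled alignment: ", nrow(x$seq), " sequences x ", ncol(x$seq),
      " sites\n", sep = "")
  for (sp in names(tab))
    cat("  ", sp, ": ", tab[[sp]], " sequence(s)\n", sep = "")
  invisible(x)
}

#' Number of sequences and alignment length
#' @param x a `labeled_alignment`.
#' @return `dim()` returns `c(n_sequences, n_sites)`.
#' @export
dim.labeled_alignment <- function(x) dim(x$seq)

#' Subset a labeled alignment by sequence
#' @param x a `labeled_alignment`.
#' @param i row (sequence) index.
#' @param ... unused.
#' @export
`[.labeled_alignment` <- function(x, i, ...) {
  labeled_alignment(x$seq[i, , drop = FALSE], x$ids[i], x$species[i])
}

#' Sequences as strings
#' @param x a `labeled_alignment`.
#' @return named character vector of sequence strings.
#' @export
alignment_strings <- function(x) {
  stopifnot(inherits(x, "labeled_alignment"))
  stats::setNames(apply(x$seq, 1L, paste, collapse = ""), x$ids)
}

## states considered observed data; anything else is missing
.DNA_STATES <- c("A", "C", "G", "T")

.is_state <- function(chars) chars %in% .DNA_STATES

.norm_string <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

.revcomp <- function(s) {
  chars <- rev(strsplit(.norm_string(s), "", fixed = TRUE)[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[chars]
  out[is.na(out)] <- chars[is.na(out)]  # ambiguity codes kept verbatim
  paste(out, collapse = "")
}

#' Read a labeled alignment from FASTA
#'
#' Species labels are parsed from a `species=` key in the FASTA header
#' (`>id species=Ursus arctos`); headers lacking the key are treated as
#' queries (label `"QUERY"`).
#'
#' @param path path to a FASTA file.
#' @return a [labeled_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("species=", headers, fixed = TRUE),
                    sub("^.*species=", "", headers), "QUERY")
  species <- trimws(species)
  labeled_alignment(as.character(ss), ids, species)
}

#' Write a labeled alignment to FASTA
#'
#' Headers carry the species label as `>id species=label`.
#'
#' @param x a `labeled_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(x, path) {
  stopifnot(inherits(x, "labeled_alignment"))
  ss <- Biostrings::BStringSet(alignment_strings(x))
  names(ss) <- paste0(x$ids, " species=", x$species)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Split an alignment into species sequences and queries
#' @param x a `labeled_alignment`.
#' @return list with `species` (non-query rows) and `query` (query rows,
#'   possibly zero-row).
#' @export
split_queries <- function(x) {
  is_q <- x$species == "QUERY"
  list(species = if (all(is_q)) NULL else x[!is_q],
       query = if (any(is_q)) x[is_q] else NULL)
}
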
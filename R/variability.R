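#' Per-site, per-species nucleotide variability table
#'
#' Tabulates, for every alignment column, the observed nucleotide state
#' counts within each species. Gaps, `N` and IUPAC ambiguity codes are
#' tallied as missing. Query sequences (label `"QUERY"`) are excluded from
#' the species statistics and reported separately, mirroring a published
#' variability table's "focal sequences" row. Columns are reported in
#' reference coordinates via the supplied mapping.
#'
#' @param alignment a [labeled_alignment()]; all sequences equal length and
#'   as long as the mapped fragment.
#' @param mapping a mapped [fragment_mapping()] supplying the reference
#'   coordinate frame; defaults to the identity frame (reference position =
#'   column index).
#' @return object of class `variability_table`: list with
#'   \describe{
#'     \item{positions}{integer reference coordinates, ascending;}
#'     \item{species}{species labels (queries excluded);}
#'     \item{counts}{named list, per species a 4 x n_positions integer
#'       matrix with rows A, C, G, T;}
#'     \item{missing}{species x positions integer matrix of missing calls;}
#'     \item{sample_sizes}{named integer vector;}
#'     \item{query}{list with `ids` and a character matrix of per-site query
#'       states, or `NULL` when the alignment has no queries.}
#'   }
#' @examples
#' tab <- tabulate_variability(build_bear_fixture(),
#'                             fragment_mapping(451, 554))
#' tab$counts[["Ursus arctos"]][, as.character(c(474, 478, 492, 550))]
#' @export
tabulate_variability <- function(alignment, mapping = NULL) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  if (nrow(alignment$seq) == 0L) stop("empty alignment")
  L <- ncol(alignment$seq)
  if (is.null(mapping)) mapping <- fragment_mapping(1L, L)
  .check_mapped(mapping)
  if (mapping$fragment_length != L)
    stop("mapping covers ", mapping$fragment_length,
         " sites but the alignment has ", L)
  positions <- fragment_to_ref(mapping, seq_len(L))
  ord <- order(positions)
  positions <- positions[ord]

  parts <- split_queries(alignment)
  sp_aln <- parts$species
  if (is.null(sp_aln)) stop("alignment contains only query sequences")
  species <- unique(sp_aln$species)

  counts <- list()
  missing <- matrix(0L, nrow = length(species), ncol = L,
                    dimnames = list(species, as.character(positions)))
  for (sp in species) {
    m <- sp_aln$seq[sp_aln$species == sp, ord, drop = FALSE]
    cnt <- matrix(0L, nrow = 4L, ncol = L,
                  dimnames = list(.DNA_STATES, as.character(positions)))
    for (s in .DNA_STATES) cnt[s, ] <- as.integer(colSums(m == s))
    counts[[sp]] <- cnt
    missing[sp, ] <- nrow(m) - colSums(cnt)
  }
  query <- NULL
  if (!is.null(parts$query)) {
    qm <- parts$query$seq[, ord, drop = FALSE]
    colnames(qm) <- as.character(positions)
    query <- list(ids = parts$query$ids, states = qm)
  }
  structure(list(positions = positions,
                 species = species,
                 counts = counts,
                 missing = missing,
                 sample_sizes = stats::setNames(
                   as.integer(table(sp_aln$species)[species]), species),
                 query = query),
            class = "variability_table")
}

#' State counts at one position for one species
#' @param table a `variability_table`.
#' @param species species label.
#' @param position reference position.
#' @return named integer vector over the observed states (zero counts
#'   dropped).
#' @export
state_counts <- function(table, species, position) {
  stopifnot(inherits(table, "variability_table"))
  if (!species %in% table$species) stop("unknown species '", species, "'")
  j <- as.character(as.integer(position))
  if (!j %in% colnames(table$counts[[species]]))
    stop("position ", position, " not in table")
  cnt <- table$counts[[species]][, j]
  cnt[cnt > 0L]
}

#' Positions variable across the pooled species
#'
#' Positions showing more than one observed state across all species pooled
#' (queries excluded).
#'
#' @param table a `variability_table`.
#' @return integer vector of reference positions, ascending.
#' @export
variable_positions <- function(table) {
  stopifnot(inherits(table, "variability_table"))
  pooled <- Reduce(`+`, table$counts)
  table$positions[colSums(pooled > 0L) > 1L]
}

#' Positions where two species differ
#'
#' Under the default `"set_or_modal"` rule a position counts as a
#' between-species difference when the two species' observed state *sets*
#' differ, or when their modal (most frequent) states differ. The modal
#' clause is what lets a site where the species share both states but at
#' sharply reversed frequencies (e.g. mostly T in one species, mostly C in
#' the other) register as a difference. The alternative `"frequency"` rule
#' flags any position where the relative state frequency distributions are
#' unequal. Modal ties are broken alphabetically.
#'
#' @param table a `variability_table`.
#' @param species_a,species_b species labels present in the table.
#' @param rule `"set_or_modal"` (default) or `"frequency"`.
#' @return integer vector of reference positions.
#' @export
between_species_differences <- function(table, species_a, species_b,
                                        rule = c("set_or_modal", "frequency")) {
  stopifnot(inherits(table, "variability_table"))
  rule <- match.arg(rule)
  for (sp in c(species_a, species_b))
    if (!sp %in% table$species) stop("unknown species '", sp, "'")
  a <- table$counts[[species_a]]
  b <- table$counts[[species_b]]
  differs <- vapply(seq_along(table$positions), function(j) {
    ca <- a[, j]; cb <- b[, j]
    if (sum(ca) == 0L || sum(cb) == 0L) return(FALSE)  # all-missing column
    if (rule == "frequency") {
      return(!isTRUE(all.equal(ca / sum(ca), cb / sum(cb))))
    }
    sets_differ <- !setequal(names(ca)[ca > 0L], names(cb)[cb > 0L])
    modal <- function(cnt) names(cnt)[which.max(cnt)]  # ties: alphabetical
    sets_differ || modal(ca) != modal(cb)
  }, logical(1L))
  table$positions[differs]
}

#' Positions polymorphic within one species
#'
#' @param table a `variability_table`.
#' @param species species label.
#' @return integer vector of positions where the species shows two or more
#'   states.
#' @export
within_species_polymorphic <- function(table, species) {
  stopifnot(inherits(table, "variability_table"))
  if (!species %in% table$species) stop("unknown species '", species, "'")
  table$positions[colSums(table$counts[[species]] > 0L) >= 2L]
}

#' @export
print.variability_table <- function(x, positions = NULL, ...) {
  if (is.null(positions)) positions <- variable_positions(x)
  if (length(positions) == 0L) {
    cat("Variability table: no variable positions among",
        length(x$positions), "sites\n")
    return(invisible(x))
  }
  cat("Variability table (variable positions only):\n")
  print(format_variability(x, positions), row.names = FALSE)
  invisible(x)
}

#' Format a variability table in the published layout
#'
#' One row per species (plus one per query set), one column per requested
#' position, cells of the form `"T (40); C (9)"`.
#'
#' @param table a `variability_table`.
#' @param positions positions to include; defaults to the variable ones.
#' @return a data.frame.
#' @export
format_variability <- function(table, positions = NULL) {
  stopifnot(inherits(table, "variability_table"))
  if (is.null(positions)) positions <- variable_positions(table)
  cols <- as.character(as.integer(positions))
  cell <- function(cnt) {
    cnt <- cnt[cnt > 0L]
    if (length(cnt) == 0L) return("-")
    paste(sprintf("%s (%d)", names(cnt), cnt), collapse = "; ")
  }
  rows <- lapply(table$species, function(sp) {
    c(species = sprintf("%s (%d)", sp, table$sample_sizes[[sp]]),
      vapply(cols, function(j) cell(table$counts[[sp]][, j]), character(1L)))
  })
  if (!is.null(table$query)) {
    qs <- vapply(cols, function(j) {
      paste(unique(table$query$states[, j]), collapse = "/")
    }, character(1L))
    rows <- c(rows, list(c(species = sprintf("Focal sequences (%d)",
                                             length(table$query$ids)), qs)))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("species", cols)
  df
}

#' Write a variability table as TSV
#' @param table a `variability_table`.
#' @param path output path.
#' @param positions positions to include; defaults to the variable ones.
#' @return `path`, invisibly.
#' @export
write_variability_tsv <- function(table, path, positions = NULL) {
  utils::write.table(format_variability(table, positions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
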
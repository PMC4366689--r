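#' Species character profiles for population aggregation analysis
#'
#' Population aggregation analysis (PAA) diagnoses species by fixed,
#' mutually exclusive character states: a site (or combination of sites)
#' is diagnostic only when the observed states of the two species do not
#' overlap in a single individual. This function builds the per-species
#' evidence: for each variable alignment position the *set* of observed
#' states, and the set of observed joint haplotypes over all variable
#' positions. Frequencies play no role — presence/absence is the
#' aggregation criterion.
#'
#' Individuals with a gap or ambiguity code at a variable position are
#' ignored at that position for set construction, and excluded from the
#' joint-haplotype set if any variable position is missing.
#'
#' @param alignment a [labeled_alignment()] (queries allowed; excluded from
#'   profiles).
#' @param mapping optional [fragment_mapping()] giving the reference frame.
#' @param positions variable positions (reference coordinates) to profile;
#'   defaults to [variable_positions()] of the tabulated alignment.
#' @return object of class `paa_profiles`: list with `positions` and, per
#'   species, `sets` (list of state sets per position) and `haplotypes`
#'   (character vector of distinct joint haplotype strings, e.g. `"TAGT"`).
#' @examples
#' prof <- species_profiles(build_bear_fixture(), fragment_mapping(451, 554))
#' prof$profiles[["Ursus maritimus"]]$sets
#' @export
species_profiles <- function(alignment, mapping = NULL, positions = NULL) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  L <- ncol(alignment$seq)
  if (is.null(mapping)) mapping <- fragment_mapping(1L, L)
  tab <- tabulate_variability(alignment, mapping)
  if (is.null(positions)) positions <- variable_positions(tab)
  positions <- sort(as.integer(positions))
  if (!all(positions %in% tab$positions))
    stop("requested positions outside the alignment's reference frame")
  frag_idx <- vapply(positions, function(p) ref_to_fragment(mapping, p),
                     integer(1L))

  parts <- split_queries(alignment)
  sp_aln <- parts$species
  profiles <- list()
  for (sp in unique(sp_aln$species)) {
    m <- sp_aln$seq[sp_aln$species == sp, frag_idx, drop = FALSE]
    ok <- .is_state(m); dim(ok) <- dim(m)
    if (!any(ok)) stop("species '", sp, "' has no usable sequences at the ",
                       "variable positions")
    sets <- lapply(seq_along(positions), function(k) {
      sort(unique(m[ok[, k], k]))
    })
    names(sets) <- as.character(positions)
    complete <- rowSums(ok) == length(positions)
    haplotypes <- if (any(complete))
      sort(unique(apply(m[complete, , drop = FALSE], 1L, paste, collapse = "")))
    else character(0)
    states <- m
    states[!ok] <- NA_character_
    colnames(states) <- as.character(positions)
    profiles[[sp]] <- list(sets = sets, haplotypes = haplotypes,
                           states = states,
                           n = nrow(m), n_complete = sum(complete))
  }
  structure(list(positions = positions, profiles = profiles),
            class = "paa_profiles")
}

#' @export
print.paa_profiles <- function(x, ...) {
  cat("PAA profiles over positions:",
      paste(x$positions, collapse = ", "), "\n")
  for (sp in names(x$profiles)) {
    p <- x$profiles[[sp]]
    cat("  ", sp, " (n=", p$n, "): haplotypes {",
        paste(p$haplotypes, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Single-site diagnostic positions between two species
#'
#' A position is diagnostic when the two species' observed state sets are
#' disjoint — no state shared by even one individual of each.
#'
#' @param profiles a [species_profiles()] result.
#' @param species_a,species_b species labels.
#' @return integer vector of diagnostic reference positions (possibly
#'   empty).
#' @export
diagnostic_sites <- function(profiles, species_a, species_b) {
  p <- .two_profiles(profiles, species_a, species_b)
  keep <- vapply(seq_along(profiles$positions), function(k) {
    length(intersect(p$a$sets[[k]], p$b$sets[[k]])) == 0L
  }, logical(1L))
  profiles$positions[keep]
}

#' Exhaustive search for diagnostic character combinations
#'
#' For each combination size `k` up to `kmax`, enumerates every k-tuple of
#' variable positions and reports those whose *projected joint haplotype
#' sets* are disjoint between the two species. The search operates on
#' observed joint haplotypes, never on products of marginal state sets: two
#' sites can be jointly diagnostic even when each overlaps marginally, and
#' conversely a shared full-length haplotype defeats every combination.
#' Each tuple is projected over the individuals with observed states at
#' *those* sites (an individual missing data elsewhere still contributes),
#' so the `k = 1` level coincides exactly with [diagnostic_sites()] and
#' diagnosability stays monotone under adding sites to a tuple.
#'
#' A combinatorial guard refuses inputs where any level would require more
#' than `guard` tuples.
#'
#' @param profiles a [species_profiles()] result.
#' @param species_a,species_b species labels.
#' @param kmax largest combination size to search (default 4).
#' @param guard maximum number of tuples per level (default 1e6).
#' @return object of class `diagnostic_report`: list with
#'   `single_site_diagnostics`, `combination_diagnostics` (per k, a list of
#'   integer position tuples), `kmax`, and the species labels.
#' @examples
#' prof <- species_profiles(build_bear_fixture(), fragment_mapping(451, 554))
#' diagnostic_combinations(prof, "Ursus arctos", "Ursus maritimus")
#' @export
diagnostic_combinations <- function(profiles, species_a, species_b,
                                    kmax = 4L, guard = 1e6) {
  kmax <- as.integer(kmax)
  if (kmax < 1L) stop("kmax must be >= 1")
  p <- .two_profiles(profiles, species_a, species_b)
  npos <- length(profiles$positions)
  kmax_eff <- min(kmax, npos)
  for (k in seq_len(kmax_eff))
    if (choose(npos, k) > guard)
      stop("combinatorial guard exceeded: choose(", npos, ", ", k,
           ") > ", format(guard, scientific = FALSE))

  ha <- p$a$states
  hb <- p$b$states
  combos <- list()
  for (k in seq_len(kmax_eff)) {
    tuples <- utils::combn(npos, k, simplify = FALSE)
    hits <- Filter(function(idx) .projection_disjoint(ha, hb, idx), tuples)
    combos[[as.character(k)]] <-
      lapply(hits, function(idx) profiles$positions[idx])
  }
  structure(list(species_a = species_a, species_b = species_b,
                 positions = profiles$positions,
                 single_site_diagnostics = diagnostic_sites(
                   profiles, species_a, species_b),
                 combination_diagnostics = combos,
                 kmax = kmax),
            class = "diagnostic_report")
}

## projected haplotypes of one species over a site tuple, using only
## individuals with observed data at every site of the tuple
.project_states <- function(states, idx) {
  sub <- states[, idx, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0L
  if (!any(keep)) return(character(0))
  unique(apply(sub[keep, , drop = FALSE], 1L, paste, collapse = ""))
}

.projection_disjoint <- function(ha, hb, idx) {
  pa <- .project_states(ha, idx)
  pb <- .project_states(hb, idx)
  if (length(pa) == 0L || length(pb) == 0L) return(FALSE)
  length(intersect(pa, pb)) == 0L
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("PAA diagnostic report: ", x$species_a, " vs ", x$species_b, "\n",
      sep = "")
  cat("  variable positions: ", paste(x$positions, collapse = ", "), "\n",
      sep = "")
  cat("  single-site diagnostics: ",
      if (length(x$single_site_diagnostics))
        paste(x$single_site_diagnostics, collapse = ", ") else "none",
      "\n", sep = "")
  for (k in names(x$combination_diagnostics)) {
    hits <- x$combination_diagnostics[[k]]
    cat("  k=", k, ": ", length(hits), " diagnostic combination(s)",
        if (length(hits)) paste0(" [",
          paste(vapply(hits, paste, character(1L), collapse = "+"),
                collapse = "; "), "]") else "", "\n", sep = "")
  }
  invisible(x)
}

#' Assign a query sequence to compatible species
#'
#' In `"site_wise"` mode (the default, and the mode behind the headline
#' verdict) a species is compatible when the query's state at *every*
#' variable position belongs to that species' observed state set. In
#' `"exact_haplotype"` mode the query's joint haplotype must itself occur
#' in the species' observed haplotype set. The verdict is `"unambiguous"`
#' with exactly one compatible species, `"ambiguous"` with several, and
#' `"unassignable"` with none (including a query missing data at all
#' variable positions).
#'
#' @param query query sequence: a string (fragment frame) or a single-row
#'   [labeled_alignment()].
#' @param profiles a [species_profiles()] result.
#' @param mapping optional [fragment_mapping()]; defaults to the identity
#'   frame over the query length.
#' @param mode `"site_wise"` or `"exact_haplotype"`.
#' @param query_id identifier recorded in the verdict.
#' @return object of class `assignment_verdict`: list with `query_id`,
#'   `mode`, `compatible_species`, `status`, and `reason` for unassignable
#'   queries.
#' @export
assign_query <- function(query, profiles, mapping = NULL,
                         mode = c("site_wise", "exact_haplotype"),
                         query_id = "query") {
  mode <- match.arg(mode)
  stopifnot(inherits(profiles, "paa_profiles"))
  if (inherits(query, "labeled_alignment")) {
    if (nrow(query$seq) != 1L) stop("assign one query at a time")
    query_id <- query$ids[1L]
    qchars <- query$seq[1L, ]
  } else {
    qchars <- strsplit(.norm_string(query), "", fixed = TRUE)[[1L]]
  }
  if (is.null(mapping)) mapping <- fragment_mapping(1L, length(qchars))
  frag_idx <- vapply(profiles$positions,
                     function(p) ref_to_fragment(mapping, p), integer(1L))
  if (any(frag_idx > length(qchars)))
    stop("query shorter than the profiled positions require")
  qstates <- qchars[frag_idx]
  usable <- .is_state(qstates)
  if (!any(usable)) {
    return(structure(list(query_id = query_id, mode = mode,
                          compatible_species = character(0),
                          status = "unassignable",
                          reason = "query missing data at all variable positions"),
                     class = "assignment_verdict"))
  }
  compatible <- character(0)
  for (sp in names(profiles$profiles)) {
    prof <- profiles$profiles[[sp]]
    ok <- if (mode == "site_wise") {
      all(vapply(which(usable), function(k)
        qstates[k] %in% prof$sets[[k]], logical(1L)))
    } else {
      all(usable) && paste(qstates, collapse = "") %in% prof$haplotypes
    }
    if (ok) compatible <- c(compatible, sp)
  }
  status <- if (length(compatible) == 0L) "unassignable"
            else if (length(compatible) == 1L) "unambiguous"
            else "ambiguous"
  structure(list(query_id = query_id, mode = mode,
                 compatible_species = compatible, status = status,
                 reason = if (status == "unassignable")
                   "no species' observed states are compatible" else NULL),
            class = "assignment_verdict")
}

#' @export
print.assignment_verdict <- function(x, ...) {
  cat("Query '", x$query_id, "' (", x$mode, "): ", x$status, sep = "")
  if (length(x$compatible_species))
    cat(" {", paste(x$compatible_species, collapse = ", "), "}", sep = "")
  if (!is.null(x$reason)) cat(" — ", x$reason, sep = "")
  cat("\n")
  invisible(x)
}

.two_profiles <- function(profiles, species_a, species_b) {
  stopifnot(inherits(profiles, "paa_profiles"))
  for (sp in c(species_a, species_b))
    if (!sp %in% names(profiles$profiles))
      stop("unknown species '", sp, "'")
  list(a = profiles$profiles[[species_a]], b = profiles$profiles[[species_b]])
}
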
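#' Marginal specification of per-site state counts
#'
#' Describes, for each species, the number of individuals and the per-site
#' nucleotide state counts at a set of variable reference positions; all
#' remaining sites of the fragment are invariant and carry
#' `background_state`. [generate_from_marginals()] turns such a spec into a
#' concrete alignment whose tabulation reproduces the counts exactly.
#'
#' @param species named list; each element is a list with `n` (number of
#'   individuals) and `sites`, itself a named list mapping reference
#'   positions (as names, e.g. `"474"`) to named integer vectors of state
#'   counts (e.g. `c(T = 40, C = 9)`). Counts at every site must sum to `n`.
#' @param fragment_start,fragment_end 1-based inclusive reference
#'   coordinates of the fragment; every variable position must lie within.
#' @param background_state single nucleotide used at all invariant sites.
#' @return object of class `marginal_spec`.
#' @export
marginal_spec <- function(species, fragment_start, fragment_end,
                          background_state = "A") {
  stopifnot(is.list(species), length(species) >= 1L,
            !is.null(names(species)))
  fragment_start <- as.integer(fragment_start)
  fragment_end <- as.integer(fragment_end)
  if (fragment_start < 1L || fragment_end < fragment_start)
    stop("invalid fragment coordinates")
  background_state <- .norm_string(background_state)
  if (!background_state %in% .DNA_STATES)
    stop("background_state must be one of A, C, G, T")
  for (sp in names(species)) {
    el <- species[[sp]]
    if (is.null(el$n) || el$n < 1L)
      stop("species '", sp, "': 'n' must be a positive count")
    for (pos in names(el$sites)) {
      p <- as.integer(pos)
      if (is.na(p) || p < fragment_start || p > fragment_end)
        stop("species '", sp, "': position ", pos,
             " lies outside the fragment [", fragment_start, ", ",
             fragment_end, "]")
      counts <- el$sites[[pos]]
      names(counts) <- .norm_string(names(counts))
      if (!all(names(counts) %in% .DNA_STATES))
        stop("species '", sp, "', position ", pos,
             ": states must be A, C, G or T")
      if (sum(counts) != el$n)
        stop("species '", sp, "', position ", pos, ": counts sum to ",
             sum(counts), ", expected n = ", el$n)
      species[[sp]]$sites[[pos]] <- counts
    }
  }
  structure(list(species = species,
                 fragment_start = fragment_start,
                 fragment_end = fragment_end,
                 background_state = background_state),
            class = "marginal_spec")
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat("Marginal spec: fragment [", x$fragment_start, ", ", x$fragment_end,
      "], background '", x$background_state, "'\n", sep = "")
  for (sp in names(x$species)) {
    el <- x$species[[sp]]
    cat("  ", sp, " (n=", el$n, "): positions ",
        paste(names(el$sites), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

## Canonical per-species joint haplotypes over the four variable sites
## (reference 474, 478, 492, 550).  Marginals at each site match the
## published per-site counts; the joint arrangement is a constrained
## completion chosen so that the full haplotype TAGT is shared between the
## two species (the real joint haplotypes are not published).
.BEAR_HAPLOTYPES <- list(
  "Ursus arctos" = list(
    c("TAGC", 34L), c("CAGC", 5L), c("CAGT", 4L), c("TGGT", 3L),
    c("TGGC", 1L), c("TGAT", 1L), c("TAGT", 1L)),
  "Ursus maritimus" = list(
    c("CAGT", 31L), c("TAGT", 1L))
)

.BEAR_POSITIONS <- c(474L, 478L, 492L, 550L)
.BEAR_START <- 451L
.BEAR_END <- 554L
.BEAR_FOCAL <- "TAGT"

#' Canonical two-species fragment fixture
#'
#' Builds the package's reference dataset: 49 Brown Bear (*Ursus arctos*)
#' and 32 Polar Bear (*Ursus maritimus*) 104-bp fragment sequences spanning
#' reference positions 451-554 of the mitochondrial 12S rRNA gene, plus two
#' identical 104-bp query ("focal") sequences. Exactly four sites are
#' variable, at reference positions 474, 478, 492 and 550 (fragment
#' positions 24, 28, 42 and 100); all other sites are invariant. The
#' per-species, per-site state counts equal the published variability table
#' (arctos: T40/C9, A44/G5, A1/G48, T9/C40; maritimus: T1/C31, A32, G32,
#' T32; focal haplotype T,A,G,T). The joint haplotypes are a fixed,
#' compiled-in completion consistent with those marginals in which the full
#' haplotype TAGT is shared by both species, so no character combination
#' can diagnose them.
#'
#' @return a [labeled_alignment()] with 83 sequences of length 104
#'   (49 "Ursus arctos", 32 "Ursus maritimus", 2 "QUERY").
#' @examples
#' fx <- build_bear_fixture()
#' table(fx$species)
#' @export
build_bear_fixture <- function() {
  L <- .BEAR_END - .BEAR_START + 1L
  frag_pos <- .BEAR_POSITIONS - .BEAR_START + 1L
  expand <- function(haps) {
    unlist(lapply(haps, function(h) rep(h[[1L]], as.integer(h[[2L]]))))
  }
  rows <- list()
  ids <- character()
  species <- character()
  for (sp in names(.BEAR_HAPLOTYPES)) {
    haps <- expand(.BEAR_HAPLOTYPES[[sp]])
    tag <- ifelse(sp == "Ursus arctos", "arctos", "maritimus")
    for (i in seq_along(haps)) {
      s <- rep("A", L)
      s[frag_pos] <- strsplit(haps[i], "", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- s
      ids <- c(ids, sprintf("%s_%02d", tag, i))
      species <- c(species, sp)
    }
  }
  for (i in 1:2) {
    s <- rep("A", L)
    s[frag_pos] <- strsplit(.BEAR_FOCAL, "", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- s
    ids <- c(ids, sprintf("focal_%02d", i))
    species <- c(species, "QUERY")
  }
  labeled_alignment(do.call(rbind, rows), ids, species)
}

#' Marginal spec matching the canonical fixture
#'
#' The per-site state counts of [build_bear_fixture()] as a
#' [marginal_spec()], for round-trip tests and as a template for user specs.
#'
#' @return a `marginal_spec`.
#' @export
bear_marginal_spec <- function() {
  marginal_spec(
    species = list(
      "Ursus arctos" = list(n = 49L, sites = list(
        "474" = c(T = 40L, C = 9L),
        "478" = c(A = 44L, G = 5L),
        "492" = c(A = 1L, G = 48L),
        "550" = c(T = 9L, C = 40L))),
      "Ursus maritimus" = list(n = 32L, sites = list(
        "474" = c(T = 1L, C = 31L),
        "478" = c(A = 32L),
        "492" = c(G = 32L),
        "550" = c(T = 32L)))),
    fragment_start = .BEAR_START, fragment_end = .BEAR_END,
    background_state = "A")
}

#' Generate an alignment with prescribed per-site state counts
#'
#' Produces an alignment whose per-species, per-site tabulation reproduces
#' the spec's counts exactly. The state counts at each site are laid out
#' independently across individuals in a random (seeded) arrangement, so
#' only the joint haplotype structure is random; the marginals are exact by
#' construction.
#'
#' @param spec a [marginal_spec()].
#' @param seed integer seed controlling the joint arrangement.
#' @return a [labeled_alignment()] covering the fragment
#'   (`fragment_end - fragment_start + 1` sites), with one row per
#'   individual and no queries.
#' @export
generate_from_marginals <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "marginal_spec"))
  rng <- .local_rng(seed)
  on.exit(rng(), add = TRUE)
  L <- spec$fragment_end - spec$fragment_start + 1L
  rows <- list(); ids <- character(); species <- character()
  for (sp in names(spec$species)) {
    el <- spec$species[[sp]]
    m <- matrix(spec$background_state, nrow = el$n, ncol = L)
    for (pos in names(el$sites)) {
      j <- as.integer(pos) - spec$fragment_start + 1L
      counts <- el$sites[[pos]]
      column <- rep(names(counts), counts)
      m[, j] <- sample(column, length(column))
    }
    rows[[sp]] <- m
    ids <- c(ids, sprintf("%s_%02d", gsub("\\s+", "_", sp), seq_len(el$n)))
    species <- c(species, rep(sp, el$n))
  }
  labeled_alignment(do.call(rbind, rows), ids, species)
}

#' Generate a random reference sequence and one of its fragments
#'
#' @param ref_length length of the reference sequence.
#' @param start,end 1-based inclusive fragment coordinates,
#'   `1 <= start <= end <= ref_length`.
#' @param seed integer seed.
#' @return list with `reference` and `fragment` strings; the fragment is
#'   the reference substring at positions `[start, end]`.
#' @export
generate_reference_and_fragment <- function(ref_length, start, end, seed = 1L) {
  ref_length <- as.integer(ref_length)
  start <- as.integer(start); end <- as.integer(end)
  if (!(1L <= start && start <= end && end <= ref_length))
    stop("require 1 <= start <= end <= ref_length")
  rng <- .local_rng(seed)
  on.exit(rng(), add = TRUE)
  chars <- sample(.DNA_STATES, ref_length, replace = TRUE)
  list(reference = paste(chars, collapse = ""),
       fragment = paste(chars[start:end], collapse = ""))
}

#' Randomly mutated copies of a base sequence
#'
#' Each site of each copy is independently substituted, with probability
#' `p`, to a uniformly chosen *different* nucleotide.
#'
#' @param base_sequence nucleotide string over A, C, G, T.
#' @param n_copies number of copies.
#' @param p per-site substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @return character vector of `n_copies` mutated strings.
#' @export
mutate_sequences <- function(base_sequence, n_copies, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1, n_copies >= 1)
  rng <- .local_rng(seed)
  on.exit(rng(), add = TRUE)
  base <- strsplit(.norm_string(base_sequence), "", fixed = TRUE)[[1L]]
  L <- length(base)
  vapply(seq_len(n_copies), function(i) {
    s <- base
    hit <- which(stats::runif(L) < p)
    for (j in hit) {
      s[j] <- sample(setdiff(.DNA_STATES, s[j]), 1L)
    }
    paste(s, collapse = "")
  }, character(1L))
}

## Seeded RNG scoped to a single generator call: saves the caller's RNG
## state and returns a restorer for on.exit().
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
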
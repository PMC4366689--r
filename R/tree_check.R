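#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per sequence pair, compared only over
#' sites where both sequences carry an unambiguous nucleotide (pairwise
#' deletion of gaps, `N` and ambiguity codes).
#'
#' @param alignment a [labeled_alignment()] or a character matrix of single
#'   characters with one row per sequence.
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   ids as dimnames; entries lie in \[0, 1\].
#' @export
p_distance_matrix <- function(alignment) {
  if (inherits(alignment, "labeled_alignment")) {
    m <- alignment$seq
    rownames(m) <- alignment$ids
  } else {
    m <- alignment
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least two sequences")
  ok <- matrix(.is_state(m), nrow = n) * 1L
  comparable <- tcrossprod(ok)
  matches <- Reduce(`+`, lapply(.DNA_STATES, function(s)
    tcrossprod((m == s) * ok)))
  off <- comparable[upper.tri(comparable)]
  if (any(off == 0))
    stop("at least one sequence pair has zero comparable sites")
  d <- (comparable - matches) / comparable
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); on an additive distance
#' matrix it recovers the generating topology and branch lengths exactly.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), isSymmetric(unname(d)))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  ape::nj(d)
}

## Non-trivial bipartitions of an unrooted tree, canonicalised to the side
## not containing the first tip label; returns keys "lab1|lab2|..." plus the
## corresponding node numbers of the input tree.
.tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  ref <- phy$tip.label[1L]
  keys <- character(0); nodes <- integer(0)
  for (i in seq_along(pp)) {
    clade <- labs[pp[[i]]]
    size <- length(clade)
    if (size < 2L || size > ntip - 2L) next
    side <- if (ref %in% clade) setdiff(labs, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ntip + i)
  }
  list(keys = keys, nodes = nodes, labels = labs)
}

.split_key <- function(labels) paste(sort(labels), collapse = "|")

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree of the alignment's p-distances, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds the
#' NJ tree of each pseudo-replicate, and reports for every non-trivial
#' bipartition of the original tree the percentage of replicate trees
#' containing it (Felsenstein's nonparametric bootstrap). Deterministic
#' given `seed`.
#'
#' @param alignment a [labeled_alignment()] (queries included as ordinary
#'   taxa if present; filter beforehand if not wanted).
#' @param n_replicates number of bootstrap pseudo-replicates (default
#'   1000).
#' @param seed integer seed (required for reproducibility).
#' @return object of class `supported_tree`: list with `tree` (the
#'   original NJ `phylo`, internal nodes labelled with rounded support),
#'   `splits` (list of tip-label vectors, one per non-trivial
#'   bipartition), `support` (percentages in \[0, 100\]), `categories`
#'   (via [classify_support()]), `n_replicates`, `seed`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed) {
  stopifnot(inherits(alignment, "labeled_alignment"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (missing(seed)) stop("'seed' is required")
  rng <- .local_rng(seed)
  on.exit(rng(), add = TRUE)

  m <- alignment$seq
  rownames(m) <- alignment$ids
  L <- ncol(m)
  phy <- neighbor_joining(p_distance_matrix(m))
  orig <- .tree_splits(phy)
  hits <- stats::setNames(integer(length(orig$keys)), orig$keys)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_phy <- tryCatch(
      neighbor_joining(p_distance_matrix(m[, cols, drop = FALSE])),
      error = function(e) NULL)  # e.g. a pair with no comparable sites
    if (is.null(rep_phy)) next
    rk <- .tree_splits(rep_phy)$keys
    found <- orig$keys %in% rk
    hits[found] <- hits[found] + 1L
  }
  support <- 100 * hits / n_replicates
  phy$node.label <- rep("", phy$Nnode)
  ntip <- length(phy$tip.label)
  phy$node.label[orig$nodes - ntip] <- as.character(round(support))
  structure(list(tree = phy,
                 splits = lapply(strsplit(orig$keys, "|", fixed = TRUE),
                                 identity),
                 support = unname(support),
                 categories = classify_support(unname(support),
                                               "bootstrap_pct"),
                 n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("NJ tree with bootstrap support (", x$n_replicates,
      " replicates, seed ", x$seed, "):\n", sep = "")
  cat("  ", length(x$tree$tip.label), " taxa, ", length(x$splits),
      " non-trivial bipartition(s)\n", sep = "")
  if (length(x$splits)) {
    tab <- table(factor(x$categories,
                        levels = c("strong", "moderate", "negligible")))
    cat("  support: ", paste(sprintf("%s %d", names(tab), tab),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Support for a specific bipartition
#'
#' Returns the bootstrap percentage of the bipartition separating
#' `label_set` from the remaining taxa, or `NA` if that bipartition is not
#' in the tree.
#'
#' @param st a [bootstrap_support()] result.
#' @param label_set character vector of tip labels.
#' @return numeric percentage or `NA`.
#' @export
split_support <- function(st, label_set) {
  stopifnot(inherits(st, "supported_tree"))
  labs <- st$tree$tip.label
  if (!all(label_set %in% labs)) stop("unknown tip labels")
  want <- .split_key(label_set)
  want_c <- .split_key(setdiff(labs, label_set))
  keys <- vapply(st$splits, .split_key, character(1L))
  i <- which(keys == want | keys == want_c)
  if (length(i) == 0L) NA_real_ else st$support[i[1L]]
}

#' Is a label set monophyletic on an unrooted tree?
#'
#' TRUE iff some edge bipartition separates exactly `label_set` from the
#' rest (sets of size 1, n-1 or n are trivially monophyletic).
#'
#' @param tree a `phylo` tree or `supported_tree`.
#' @param label_set character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, label_set) {
  if (inherits(tree, "supported_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!all(label_set %in% labs)) stop("unknown tip labels")
  k <- length(unique(label_set))
  n <- length(labs)
  if (k %in% c(1L, n - 1L, n)) return(TRUE)
  keys <- .tree_splits(tree)$keys
  .split_key(label_set) %in% keys ||
    .split_key(setdiff(labs, label_set)) %in% keys
}

#' Categorise a support value
#'
#' Bootstrap percentages: strong >= 75, moderate in (50, 75), negligible
#' <= 50. Posterior probabilities: strong >= 0.95, moderate in
#' \[0.90, 0.95), negligible < 0.90.
#'
#' @param value support value(s); percentages in \[0, 100\] or posterior
#'   probabilities in \[0, 1\] depending on `scale`.
#' @param scale `"bootstrap_pct"` or `"posterior_prob"`.
#' @return character vector of `"strong"`, `"moderate"`, `"negligible"`.
#' @examples
#' classify_support(c(75, 74, 50), "bootstrap_pct")
#' classify_support(c(0.95, 0.94, 0.89), "posterior_prob")
#' @export
classify_support <- function(value, scale = c("bootstrap_pct",
                                              "posterior_prob")) {
  scale <- match.arg(scale)
  if (scale == "bootstrap_pct") {
    if (any(value < 0 | value > 100)) stop("bootstrap values lie in [0, 100]")
    ifelse(value >= 75, "strong",
           ifelse(value > 50, "moderate", "negligible"))
  } else {
    if (any(value < 0 | value > 1)) stop("posterior probabilities lie in [0, 1]")
    ifelse(value >= 0.95, "strong",
           ifelse(value >= 0.90, "moderate", "negligible"))
  }
}

#' Write a supported tree as newick with support node labels
#' @param st a `supported_tree` (or plain `phylo`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_supported_tree <- function(st, path) {
  phy <- if (inherits(st, "supported_tree")) st$tree else st
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Bipartition support table
#' @param st a `supported_tree`.
#' @return data.frame with one row per non-trivial bipartition: the side
#'   (as `|`-joined labels), support percentage and category.
#' @export
support_table <- function(st) {
  stopifnot(inherits(st, "supported_tree"))
  data.frame(bipartition = vapply(st$splits, paste, character(1L),
                                  collapse = "|"),
             support_pct = st$support,
             category = st$categories,
             stringsAsFactors = FALSE)
}
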
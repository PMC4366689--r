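# Independent brute-force oracles and random-data generators used across the
# suite. Each oracle is a naive re-derivation of the quantity under test and
# deliberately shares no code with the package internals.

DNA <- c("A", "C", "G", "T")

random_alignment <- function(n, L, n_species = 2, seed = 1,
                             missing_prob = 0) {
  set.seed(seed)
  m <- matrix(sample(DNA, n * L, replace = TRUE), nrow = n)
  if (missing_prob > 0) {
    hit <- matrix(runif(n * L) < missing_prob, nrow = n)
    m[hit] <- sample(c("N", "-", "R"), sum(hit), replace = TRUE)
  }
  labeled_alignment(m, paste0("s", seq_len(n)),
                    paste0("sp", rep_len(seq_len(n_species), n)))
}

# naive per-column, per-species state counting
oracle_counts <- function(aln, species, position_index) {
  rows <- which(aln$species == species)
  col <- aln$seq[rows, position_index]
  sapply(DNA, function(s) sum(col == s))
}

# positions (column indices) with >1 pooled state, queries excluded
oracle_variable_cols <- function(aln) {
  rows <- which(aln$species != "QUERY")
  which(apply(aln$seq[rows, , drop = FALSE], 2L, function(col)
    length(unique(col[col %in% DNA])) > 1L))
}

# per-species observed state sets and joint haplotypes over given columns
oracle_profile <- function(aln, species, cols) {
  m <- aln$seq[aln$species == species, cols, drop = FALSE]
  sets <- lapply(seq_along(cols), function(k) {
    v <- m[, k]
    sort(unique(v[v %in% DNA]))
  })
  complete <- apply(m, 1L, function(r) all(r %in% DNA))
  haps <- if (any(complete))
    sort(unique(apply(m[complete, , drop = FALSE], 1L, paste, collapse = "")))
  else character(0)
  list(sets = sets, haplotypes = haps)
}

# brute-force diagnostic k-tuples: project each species' individuals over
# the tuple's columns, keeping only individuals fully observed there
oracle_diag_tuples <- function(aln, sp_a, sp_b, cols, k) {
  proj <- function(sp, idx) {
    m <- aln$seq[aln$species == sp, cols[idx], drop = FALSE]
    keep <- apply(m, 1, function(r) all(r %in% DNA))
    if (!any(keep)) return(character(0))
    unique(apply(m[keep, , drop = FALSE], 1, paste, collapse = ""))
  }
  tuples <- utils::combn(length(cols), k, simplify = FALSE)
  Filter(function(idx) {
    pa <- proj(sp_a, idx); pb <- proj(sp_b, idx)
    length(pa) > 0 && length(pb) > 0 && length(intersect(pa, pb)) == 0
  }, tuples)
}

# brute-force best ungapped segment score over both strands
oracle_best_score <- function(q, s, reward = 1, penalty = -2) {
  qc <- strsplit(q, "")[[1]]
  one_strand <- function(sc) {
    n <- length(sc); m <- length(qc); best <- 0
    for (qa in 1:m) for (qb in qa:m) for (sa in 1:n) {
      sb <- sa + (qb - qa)
      if (sb > n) next
      seg <- sum(ifelse(qc[qa:qb] == sc[sa:sb], reward, penalty))
      if (seg > best) best <- seg
    }
    best
  }
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(s, "")[[1]]])
  max(one_strand(strsplit(s, "")[[1]]), one_strand(unname(rc)))
}

# naive pairwise p-distance with pairwise deletion
oracle_p_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% DNA & m[j, ] %in% DNA
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

# random unrooted binary tree with positive branch lengths, plus its
# additive distance matrix (path lengths between tips)
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_taxa, rooted = FALSE,
                    br = function(k) runif(k, 0.1, 1))
  list(tree = phy, d = ape::cophenetic.phylo(phy))
}

# unrooted topology equality via symmetric difference of bipartitions
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

bear_expected <- list(
  "Ursus arctos" = list("474" = c(T = 40, C = 9), "478" = c(A = 44, G = 5),
                        "492" = c(A = 1, G = 48), "550" = c(T = 9, C = 40)),
  "Ursus maritimus" = list("474" = c(T = 1, C = 31), "478" = c(A = 32),
                           "492" = c(G = 32), "550" = c(T = 32)))
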
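test_that("p-distances equal naive pairwise counting (and ape's raw model)", {
  for (case in 1:8) {
    aln <- random_alignment(sample(3:8, 1), sample(20:60, 1), 2,
                            seed = 1400 + case, missing_prob = 0.05)
    d <- p_distance_matrix(aln)
    expect_true(isSymmetric(unname(d)))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(d), oracle_p_distance(aln$seq), label = case)
  }

  # cross-check against ape's raw distance with pairwise deletion
  aln <- random_alignment(6, 50, 2, seed = 1490)
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln$seq)),
                                   model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(p_distance_matrix(aln)), unname(d_ape))

  # identical sequences -> all zeros
  same <- labeled_alignment(rep("ACGTACGT", 4), species = rep("s", 4))
  expect_true(all(p_distance_matrix(same) == 0))

  # the two focal fixture sequences are identical
  fx <- build_bear_fixture()
  qs <- split_queries(fx)$query
  d <- p_distance_matrix(labeled_alignment(rbind(qs$seq, qs$seq[1, ]),
                                           c("q1", "q2", "q3"),
                                           rep("QUERY", 3)))
  expect_equal(d["q1", "q2"], 0)

  # zero comparable sites is an error
  bad <- labeled_alignment(c("ANN", "NAN", "NNA"), species = rep("s", 3))
  expect_error(p_distance_matrix(bad), "comparable")
})

test_that("NJ recovers additive trees exactly", {
  # fixed 4-taxon additive matrix from a known tree
  case <- random_additive_case(4, seed = 51)
  phy <- neighbor_joining(case$d)
  expect_true(same_topology(phy, case$tree))
  # branch lengths: total tree length is preserved on additive input
  expect_equal(sum(phy$edge.length), sum(case$tree$edge.length),
               tolerance = 1e-10)
  # and all pairwise path lengths are reproduced
  expect_equal(ape::cophenetic.phylo(phy)[rownames(case$d), colnames(case$d)],
               case$d, tolerance = 1e-10)

  # random additive matrices, n <= 8
  for (s in 1:15) {
    case <- random_additive_case(sample(4:8, 1), seed = 1500 + s)
    phy <- neighbor_joining(case$d)
    expect_true(same_topology(phy, case$tree), label = s)
  }

  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("monophyly queries agree with brute-force bipartition checks", {
  case <- random_additive_case(6, seed = 61)
  phy <- case$tree
  labs <- phy$tip.label

  # brute force: enumerate all edges, collect both sides
  sides <- list()
  for (e in seq_len(nrow(phy$edge))) {
    node <- phy$edge[e, 2]
    tips <- if (node <= length(labs)) labs[node]
            else ape::extract.clade(phy, node)$tip.label
    sides <- c(sides, list(sort(tips)), list(sort(setdiff(labs, tips))))
  }
  for (trial in 1:20) {
    set.seed(1600 + trial)
    pick <- sample(labs, sample(2:4, 1))
    want <- any(vapply(sides, function(s) setequal(s, pick), logical(1)))
    expect_equal(is_monophyletic(phy, pick), want,
                 label = paste(trial, paste(pick, collapse = ",")))
  }

  expect_true(is_monophyletic(phy, labs[1]))        # single tip
  expect_true(is_monophyletic(phy, labs))           # whole taxon set
  expect_true(is_monophyletic(phy, labs[-1]))       # all but one
  expect_error(is_monophyletic(phy, "no_such_tip"), "unknown")
})

test_that("two clearly divergent clusters get full bootstrap support", {
  # 20 fixed differences between clusters, none within
  a <- strrep("A", 20); b <- strrep("C", 20)
  aln <- labeled_alignment(c(a, a, a, b, b, b),
                           ids = c("a1", "a2", "a3", "b1", "b2", "b3"),
                           species = rep(c("A", "B"), each = 3))
  st <- bootstrap_support(aln, n_replicates = 50, seed = 5)
  expect_s3_class(st, "supported_tree")
  expect_true(all(st$support >= 0 & st$support <= 100))
  sup <- split_support(st, c("a1", "a2", "a3"))
  expect_equal(sup, 100)
  expect_equal(classify_support(sup, "bootstrap_pct"), "strong")
  expect_true(is_monophyletic(st, c("b1", "b2", "b3")))
})

test_that("a single bootstrap replicate yields only 0 or 100", {
  aln <- random_alignment(6, 30, 2, seed = 71)
  st <- bootstrap_support(aln, n_replicates = 1, seed = 9)
  expect_true(all(st$support %in% c(0, 100)))
})

test_that("bootstrap support is deterministic given the seed", {
  aln <- random_alignment(6, 30, 2, seed = 73)
  s1 <- bootstrap_support(aln, n_replicates = 20, seed = 42)
  s2 <- bootstrap_support(aln, n_replicates = 20, seed = 42)
  expect_identical(s1$support, s2$support)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_error(bootstrap_support(aln, 10), "seed")
})

test_that("support classification matches the published thresholds", {
  expect_equal(classify_support(c(100, 75, 74.9, 50.1, 50, 0),
                                "bootstrap_pct"),
               c("strong", "strong", "moderate", "moderate", "negligible",
                 "negligible"))
  expect_equal(classify_support(c(1, 0.95, 0.949, 0.90, 0.899, 0),
                                "posterior_prob"),
               c("strong", "strong", "moderate", "moderate", "negligible",
                 "negligible"))
  expect_error(classify_support(101, "bootstrap_pct"), "\\[0, 100\\]")
  expect_error(classify_support(1.2, "posterior_prob"), "\\[0, 1\\]")

  # total monotone step function: category never improves as support drops
  ranks <- c(strong = 3, moderate = 2, negligible = 1)
  vals <- seq(100, 0, by = -0.5)
  expect_true(all(diff(ranks[classify_support(vals, "bootstrap_pct")]) <= 0))
})

test_that("newick output carries support as internal node labels", {
  a <- strrep("AG", 10); b <- strrep("CT", 10)
  aln <- labeled_alignment(c(a, a, b, b, strrep("AT", 10)),
                           ids = paste0("t", 1:5),
                           species = rep("s", 5))
  st <- bootstrap_support(aln, n_replicates = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_supported_tree(st, path)
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, paste0("t", 1:5))
  expect_true(any(nzchar(reread$node.label)))

  tab <- support_table(st)
  expect_equal(nrow(tab), length(st$splits))
  expect_true(all(tab$category %in% c("strong", "moderate", "negligible")))
})
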
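fixture_profiles <- function() {
  species_profiles(build_bear_fixture(), fragment_mapping(451, 554))
}

test_that("species profiles collect observed state sets and joint haplotypes", {
  prof <- fixture_profiles()
  pm <- prof$profiles[["Ursus maritimus"]]
  expect_equal(pm$sets, list("474" = c("C", "T"), "478" = "A",
                             "492" = "G", "550" = "T"))
  expect_equal(pm$haplotypes, c("CAGT", "TAGT"))

  # single-sequence species -> singleton sets
  aln <- labeled_alignment(c("ACGT", "AGGA"), species = c("a", "b"))
  p1 <- species_profiles(aln)
  expect_true(all(lengths(p1$profiles[["a"]]$sets) == 1L))

  # random data equals naive set construction
  for (case in 1:10) {
    aln <- random_alignment(10, 8, 2, seed = 800 + case, missing_prob = 0.15)
    vp <- oracle_variable_cols(aln)
    if (length(vp) == 0) next
    prof <- species_profiles(aln)
    for (sp in c("sp1", "sp2")) {
      want <- oracle_profile(aln, sp, vp)
      got <- prof$profiles[[sp]]
      expect_equal(unname(got$sets), want$sets, label = paste(case, sp))
      expect_equal(got$haplotypes, want$haplotypes, label = paste(case, sp))
    }
  }
})

test_that("no single site diagnoses the two bear species on the fixture", {
  prof <- fixture_profiles()
  expect_length(diagnostic_sites(prof, "Ursus arctos", "Ursus maritimus"),
                0L)
})

test_that("a fixed difference at one site is diagnostic", {
  aln <- labeled_alignment(c("ATG", "ATG", "ACG", "ACG"),
                           species = c("a", "a", "b", "b"))
  prof <- species_profiles(aln)
  expect_equal(diagnostic_sites(prof, "a", "b"), 2L)
})

test_that("no character combination up to k=4 separates the fixture species", {
  prof <- fixture_profiles()
  rep4 <- diagnostic_combinations(prof, "Ursus arctos", "Ursus maritimus",
                                  kmax = 4)
  expect_length(rep4$single_site_diagnostics, 0L)
  for (k in names(rep4$combination_diagnostics))
    expect_length(rep4$combination_diagnostics[[k]], 0L)
})

test_that("joint combinations differ from products of marginal sets", {
  # species a: haplotypes {AC, CA}; species b: {AA, CC}: each site overlaps
  # marginally ({A,C} at both), but the joint pairs are disjoint
  aln <- labeled_alignment(c("AC", "CA", "AA", "CC"),
                           species = c("a", "a", "b", "b"))
  prof <- species_profiles(aln)
  expect_length(diagnostic_sites(prof, "a", "b"), 0L)
  rep2 <- diagnostic_combinations(prof, "a", "b", kmax = 2)
  expect_length(rep2$combination_diagnostics[["1"]], 0L)
  expect_equal(rep2$combination_diagnostics[["2"]], list(c(1L, 2L)))
})

test_that("combination search equals brute-force enumeration on random data", {
  for (case in 1:25) {
    set.seed(900 + case)
    n_sites <- sample(2:8, 1)
    aln <- random_alignment(sample(4:12, 1), n_sites, 2, seed = 900 + case,
                            missing_prob = 0.1)
    vp <- oracle_variable_cols(aln)
    if (length(vp) < 2) next
    prof <- species_profiles(aln)
    rep3 <- diagnostic_combinations(prof, "sp1", "sp2",
                                    kmax = min(3, length(vp)))
    for (k in seq_len(min(3, length(vp)))) {
      want <- oracle_diag_tuples(aln, "sp1", "sp2", vp, k)
      want_pos <- lapply(want, function(idx) vp[idx])
      expect_equal(rep3$combination_diagnostics[[as.character(k)]],
                   want_pos, ignore_attr = TRUE,
                   label = paste(case, "k", k))
    }
    # k=1 equals the single-site rule
    expect_equal(as.integer(unlist(rep3$combination_diagnostics[["1"]])),
                 as.integer(diagnostic_sites(prof, "sp1", "sp2")))
  }
})

test_that("diagnostic tuples are monotone under superset extension", {
  for (case in 1:10) {
    aln <- random_alignment(8, 6, 2, seed = 1100 + case)
    vp <- oracle_variable_cols(aln)
    if (length(vp) < 3) next
    prof <- species_profiles(aln)
    rep3 <- diagnostic_combinations(prof, "sp1", "sp2",
                                    kmax = min(3, length(vp)))
    cd <- rep3$combination_diagnostics
    for (k in 1:2) {
      if (!as.character(k + 1) %in% names(cd)) next
      sup_keys <- vapply(cd[[as.character(k + 1)]], paste, character(1),
                         collapse = "+")
      for (tup in cd[[as.character(k)]]) {
        others <- setdiff(vp, tup)
        for (o in others) {
          key <- paste(sort(c(tup, o)), collapse = "+")
          expect_true(key %in% sup_keys,
                      label = paste("superset of", paste(tup, collapse = "+")))
        }
      }
    }
  }
})

test_that("a shared full haplotype defeats every combination", {
  # every projection of a shared haplotype is shared
  aln <- labeled_alignment(c("ACGT", "TCGA", "ACGT", "AGCT"),
                           species = c("a", "a", "b", "b"))
  prof <- species_profiles(aln)
  repx <- diagnostic_combinations(prof, "a", "b", kmax = 4)
  expect_length(repx$single_site_diagnostics, 0L)
  expect_true(all(lengths(repx$combination_diagnostics) == 0L))
})

test_that("the combinatorial guard refuses oversized searches", {
  prof <- fixture_profiles()
  expect_error(diagnostic_combinations(prof, "Ursus arctos",
                                       "Ursus maritimus", kmax = 2,
                                       guard = 2),
               "guard")
  expect_error(diagnostic_combinations(prof, "Ursus arctos", "nope"),
               "unknown species")
})

test_that("query assignment follows the compatibility rules", {
  fx <- build_bear_fixture()
  prof <- fixture_profiles()
  map <- fragment_mapping(451, 554)
  queries <- split_queries(fx)$query

  # both focal queries: ambiguous between the two species, in both modes
  for (i in 1:2) {
    v <- assign_query(queries[i], prof, map)
    expect_equal(v$status, "ambiguous")
    expect_setequal(v$compatible_species,
                    c("Ursus arctos", "Ursus maritimus"))
    vh <- assign_query(queries[i], prof, map, mode = "exact_haplotype")
    expect_equal(vh$status, "ambiguous")
  }

  # a state unseen in either species -> unassignable
  alien <- alignment_strings(queries[1])
  substr(alien, 28, 28) <- "C"  # no species shows C at reference 478
  va <- assign_query(unname(alien), prof, map)
  expect_equal(va$status, "unassignable")
  expect_length(va$compatible_species, 0L)

  # all variable positions missing -> unassignable with reason
  blank <- alignment_strings(queries[1])
  for (p in c(24, 28, 42, 100)) substr(blank, p, p) <- "N"
  vb <- assign_query(unname(blank), prof, map)
  expect_equal(vb$status, "unassignable")
  expect_match(vb$reason, "missing")

  # random queries vs random profiles equal the brute-force check
  for (case in 1:10) {
    aln <- random_alignment(8, 6, 2, seed = 1200 + case)
    vp <- oracle_variable_cols(aln)
    if (length(vp) == 0) next
    profr <- species_profiles(aln)
    q <- paste(sample(DNA, 6, replace = TRUE), collapse = "")
    got <- assign_query(q, profr)
    qc <- strsplit(q, "")[[1]]
    want <- Filter(function(sp) {
      o <- oracle_profile(aln, sp, vp)
      all(vapply(seq_along(vp), function(k)
        qc[vp[k]] %in% o$sets[[k]], logical(1)))
    }, c("sp1", "sp2"))
    expect_setequal(got$compatible_species, want)
  }
})

test_that("exact-haplotype mode is stricter than site-wise mode", {
  # query haplotype AT: each state occurs in species a (AA, TT) but the
  # joint haplotype does not
  aln <- labeled_alignment(c("AA", "TT", "CC", "CC"),
                           species = c("a", "a", "b", "b"))
  prof <- species_profiles(aln)
  site_wise <- assign_query("AT", prof)
  exact <- assign_query("AT", prof, mode = "exact_haplotype")
  expect_equal(site_wise$compatible_species, "a")
  expect_equal(site_wise$status, "unambiguous")
  expect_equal(exact$status, "unassignable")
})
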
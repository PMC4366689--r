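---
title: "Character-based identification of short mtDNA fragments"
author: "fragdiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-based identification of short mtDNA fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdiag)
```

## The problem

Short mitochondrial fragments — a hundred or so base pairs of the 12S rRNA
gene is the motivating case — are routinely used to assign unidentified
biological material to a species. Whether such an assignment is *possible*
depends entirely on whether the fragment carries character states that are
fixed in one candidate species and absent from the other. For closely
related species pairs that share mitochondrial variation through
incomplete lineage sorting or past gene flow (Brown Bear, *Ursus arctos*,
and Polar Bear, *U. maritimus*, are the canonical example), a fragment can
be too short and too conserved to separate them, and similarity scores or
gene trees built from it will not rescue the identification.

`fragdiag` implements the complete desk workflow for answering this
question for a query fragment against a two-species reference panel:

1. **refmap** — place the fragment on a reference gene sequence and set up
   the coordinate frame;
2. **variability** — tabulate per-site, per-species nucleotide state
   counts;
3. **paa** — population aggregation analysis: search for diagnostic sites
   and diagnostic character *combinations*, and assign queries by
   compatibility;
4. **blast_score** — Karlin–Altschul ungapped similarity scoring and
   tie-aware ranking of the panel against the query;
5. **tree_check** — a p-distance neighbor-joining tree with nonparametric
   bootstrap, plus the categorical support thresholds used to read it.

A synthetic-data module generates alignments with exactly prescribed
per-site state counts, so every stage is testable without any sequence
download.

## The canonical fixture

`build_bear_fixture()` is the package's reference dataset: 49 *U.
arctos* and 32 *U. maritimus* sequences of a 104-bp fragment spanning
reference positions 451–554 of the 12S gene, plus two identical focal
(query) sequences. Exactly four sites vary, at reference positions 474,
478, 492 and 550 (fragment positions 24, 28, 42, 100):

```{r}
tab <- tabulate_variability(build_bear_fixture(), fragment_mapping(451, 554))
format_variability(tab)
```

The per-species *marginal* counts at these four sites are fixed
constants of the package. The *joint* haplotypes are not derivable from
marginal counts alone, so the fixture compiles in one specific completion
that (a) reproduces every marginal count exactly and (b) contains a full
four-site haplotype, `TAGT`, observed in both species (one *arctos*
individual and one *maritimus* individual). Property (b) is the essential
structural feature: a haplotype shared between the species defeats every
character combination, which is exactly the situation the fixture is meant
to exhibit. Any completion with that property encodes the same
qualitative biology; results at the combination level are therefore
properties of this constructed fixture, not of unpublished real
haplotypes.

All background (invariant) sites carry `A`. The choice is arbitrary and
invisible to every statistic in the package, all of which either operate
on variable sites only or treat all matches alike.

## Population aggregation analysis

PAA aggregates two populations unless some character — or some joint
combination of characters — shows fixed, mutually exclusive states. The
criterion is pure presence/absence: a site where the species overlap in
even *one* individual is non-diagnostic, whatever the frequencies. This
is deliberately conservative; a frequency-based classifier would happily
"assign" the focal sequences here, and would be wrong to, because a single
shared individual proves the character state is not fixed.

Three decisions shape the implementation:

* **Joint haplotypes, never marginal products.** A pair of sites is
  diagnostic only if the *observed* joint state pairs are disjoint between
  species. Testing the Cartesian product of per-site sets instead would
  miss combinations that are jointly diagnostic despite marginal overlap,
  and falsely report ones that are marginally disjoint only in
  combination. `diagnostic_combinations()` enumerates all k-tuples of
  variable sites exhaustively (guarded at $10^6$ tuples per level,
  `kmax = 4` by default — the fixture's variable-site count).
* **Missing data.** An individual with a gap or ambiguity code at a
  variable site is skipped at that site for state-set construction, and a
  k-tuple is projected over the individuals observed at *those* k sites.
  This keeps the `k = 1` level of the combination search identical to the
  single-site rule and makes diagnosability monotone: adding a site to a
  diagnostic tuple can only shrink each species' projected haplotype set,
  never un-separate them. (The profile's full-length haplotype set,
  used by the `exact_haplotype` assignment mode, does require complete
  data at all variable sites.)
* **Two assignment modes.** `site_wise` (default) accepts a species if the
  query's state at every variable site is among that species' observed
  states; `exact_haplotype` additionally requires the query's joint
  haplotype to have been observed. The default is the weaker test, which
  is the right polarity for the headline question: if even the weak test
  leaves both species compatible, no character-based identification is
  possible.

On the fixture, the verdict is the expected stalemate:

```{r}
fx <- build_bear_fixture()
prof <- species_profiles(fx, fragment_mapping(451, 554))
diagnostic_combinations(prof, "Ursus arctos", "Ursus maritimus")
assign_query(split_queries(fx)$query[1], prof, fragment_mapping(451, 554))
```

## Similarity scoring

`best_ungapped_score()` computes the maximal-scoring ungapped segment over
every diagonal and both strands (matches `+1`, mismatches `-2` by
default; ambiguity codes never match), floored at the empty segment. Raw
scores are converted to bit scores via the Karlin–Altschul transform

$$S' = \frac{\lambda S - \ln K}{\ln 2},$$

with the standard megablast constants $\lambda = 1.28$, $K = 0.46$ as
defaults; all four constants are configurable in `scoring_params()`.
Displayed scores are rounded half-away-from-zero to integers, which is how
score lists are conventionally printed; ranking ties are defined on the
*displayed* integer, with a stable sort by subject id inside a tie group
so the ranking is invariant to database order. Under these defaults a
perfect ungapped 104-nt match scores $104$ raw $= 193$ displayed bits.
E-values use $E = K m n e^{-\lambda S}$ with no effective-length (edge)
correction — a documented simplification appropriate for fragment-scale
queries.

A subject with a single interior mismatch on this fragment scores
$103 - 2 = 101$ raw $\approx 187.6$ bits, displayed 188. Note that a
mismatch within two positions of either end scores higher than an interior
one, because trimming the mismatched prefix/suffix beats paying the
penalty; the second-tier score of a real database search therefore depends
on the alignment geometry of the database sequences, and the package makes
no claim about it beyond "strictly below the perfect tier".

## The tree check

The tree stage is deliberately lightweight: p-distances (pairwise
deletion of non-`ACGT` characters; an error if a pair has no comparable
site), neighbor joining (via `ape::nj`, which recovers additive matrices
exactly), and Felsenstein's nonparametric bootstrap — resample alignment
columns with replacement, rebuild the tree, and report for each
non-trivial bipartition of the original tree the percentage of replicates
containing it. Full likelihood or Bayesian tree inference is out of the
package's scope on purpose: the question the tree check answers is
qualitative — *does the fragment support reciprocal monophyly of the two
species?* — and a distance tree with bootstrap answers it at desk scale.
Support values are read through the conventional categories, exposed as
`classify_support()`: for bootstrap percentages, strong $\geq 75$,
moderate in $(50, 75)$, negligible $\leq 50$; for posterior
probabilities, strong $\geq 0.95$, moderate in $[0.90, 0.95)$, negligible
$< 0.90$. The posterior scale is included as a pure classifier even
though the package performs no Bayesian inference, so that externally
obtained posterior values can be read through the same categories.

Because the fixture's species share haplotypes, the *arctos*|*maritimus*
bipartition is typically absent from the NJ tree outright, and when a
resampling happens to produce it, its support is far below 50%. The test
suite checks this over ten independent 1000-replicate runs.

Default replicates: 1000. A seed is mandatory — bootstrap percentages are
Monte-Carlo estimates and are only reproducible jointly with the seed.

## Coordinate conventions and other numerical choices

* All coordinates are 1-based inclusive, in two frames: *reference*
  (position in the full gene) and *fragment* (position in the query).
  `ref_to_fragment()`/`fragment_to_ref()` convert between them and are
  exact inverses over the mapped window; reference position 474 is
  fragment position 24 under the canonical 451–554 mapping.
* Fragment placement is ungapped only, maximizing matches over both
  strands; ties prefer the forward strand, then the leftmost offset. The
  default acceptance threshold is identity $\geq 0.8$, an arbitrary but
  logged and configurable guard against nonsense placements; below it an
  explicit *unmapped* result is returned rather than an error.
* Input is case-insensitive and `U` is read as `T`. Characters outside
  `{A, C, G, T}` are treated as missing data everywhere (never as
  matches, never as states).
* A "between-species difference" position (for the summary table) is one
  where the species' observed state sets differ *or* their modal states
  differ, with modal ties broken alphabetically; the modal clause lets a
  site with shared states but sharply reversed majorities count as a
  difference. A frequency-distribution-inequality rule is available as a
  configurable alternative; both rules report the same four positions on
  the fixture.
* `within_species_polymorphic()` counts any site where a species shows two
  or more observed states — singleton variants count. On the fixture this
  yields four polymorphic sites for *U. arctos* (the minor state at
  position 492 is a single individual) and one for *U. maritimus*.

## What the generator does and does not emulate

`generate_from_marginals()` reproduces prescribed per-site state counts
exactly, randomizing only the arrangement of states across individuals
(independently per site). It emulates the *marginal* structure of a real
two-species alignment perfectly, by construction. It does not emulate:
linkage between sites (joint haplotype structure is random unless
compiled in, as the canonical fixture's is), phylogenetic correlation
among individuals, indels, sequencing error, or ambiguity codes. Passing
tests on generated data therefore demonstrate correctness of the counting
and search machinery, not robustness to alignment error or to haplotype
structures other than those constructed. `mutate_sequences()` adds i.i.d.
per-site substitutions (each hit site moves to a uniformly chosen
*different* state) for mapping and ranking tests.

## Problem sizes in the test suite

The suite runs the canonical 83-sequence fixture end to end; randomized
property tests use alignments of up to ~20 sequences and ~60 sites with
up to 8 variable sites (the scale at which exhaustive brute-force oracles
stay instant); NJ recovery is checked on additive matrices of up to 8
taxa; the bootstrap stochasticity check uses ten independent runs of 1000
replicates on the 81 database sequences. These sizes were chosen so each
oracle comparison is exhaustive rather than sampled wherever
exhaustiveness is feasible.

## Known limitations

* Diagnosis is pairwise (two species at a time); multi-species panels are
  iterated pairwise by the caller.
* Combination-level results on the canonical fixture reflect its
  compiled-in joint haplotype completion (see above).
* The scoring stage reproduces the score *structure* of a database
  search (perfect tier, strictly lower mismatch tiers, tie-group sizes),
  not the composition of any external database.
* No gapped alignment, masking, or length-corrected E-values; no
  likelihood or Bayesian tree inference.
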
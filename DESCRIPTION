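Package: fragdiag
Title: Character-Based Species Diagnosis of Short Mitochondrial Sequence Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether a short mitochondrial DNA fragment
    (such as a 104-bp stretch of the 12S rRNA gene) can be assigned to a
    species. Implements ungapped placement of a query fragment on a
    reference gene with coordinate conversion, per-site per-species
    nucleotide variability tables, population aggregation analysis
    (diagnostic sites and exhaustive diagnostic character combinations,
    with query assignment verdicts), Karlin-Altschul ungapped similarity
    scoring with bit scores, E-values and tie-aware database ranking, and
    a p-distance neighbor-joining tree check with nonparametric bootstrap
    support and categorical support classification. A synthetic-data
    module generates alignments with prescribed per-site state counts so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
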
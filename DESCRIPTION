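Package: refclust
Title: Taxonomy-Aware Curation of DNA Barcode Reference Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns a raw FASTA file plus an accession-to-lineage taxonomy
    map into a curated, redundancy-reduced, QIIME-formatted DNA barcode
    reference dataset. Implements record-level cleaning (header-keyword
    screening, minimum-length trimming, ITS1-5.8S-ITS2 concatenation,
    exclusion lists), a self-contained greedy incremental clusterer
    following the CD-HIT convention (longest-sequence representatives,
    identity relative to the shorter sequence), and a taxonomy-aware
    cluster evaluation step that checks each cluster for a dominant
    species (strictly more than 90 percent of informative members),
    escalates to genus and family when the species check fails, blanks
    unresolved ranks to NA, re-selects representatives from the dominant
    taxon, flags multi-species clusters, and discards clusters that fail
    at family level with a full per-member log for manual review. A
    deterministic synthetic-fixture generator with hierarchical taxa,
    controlled divergence, mislabeled records and flagged header keywords
    makes the whole pipeline testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
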
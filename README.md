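# refclust

Taxonomy-aware curation of DNA barcode reference databases in R.

## The problem

Taxonomic profiling by DNA metabarcoding stands or falls with the
reference database the reads are classified against. Reference sequences
pulled from GenBank arrive redundant (thousands of near-identical entries
per common species), noisy (definition lines flagged "predicted",
"unverified", ...), and occasionally misidentified — most notoriously,
fungal ITS sequences deposited under plant names. Plain dereplication with
a greedy clusterer such as CD-HIT compounds the last problem: it keeps the
*longest* sequence of each cluster, so a single mislabeled long sequence
can become the representative for a cluster of correctly identified ones.

`refclust` implements the full curation path from a raw FASTA plus an
accession → lineage map to a QIIME-formatted reference set:

1. **Record-level cleaning** — drop records whose description contains any
   of `predicted, putative, uncharacterized, unverified, scaffold,
   protein, hypothetical` (case-insensitive substrings); drop sequences
   shorter than 150 nt; optionally concatenate ITS1 + 5.8S + ITS2 region
   files into full-ITS records; optionally drop an exclusion list of
   reviewed accessions.
2. **Greedy incremental clustering** (`greedyCluster()`) at 99% identity,
   following the CD-HIT convention: sequences processed longest-first,
   first-fit against existing representatives, identity computed from an
   optimal global alignment as
   `matches / length(shorter sequence)`. A self-contained aligner (C++
   Needleman–Wunsch, linear gaps) means no external binaries; existing
   CD-HIT `.clstr` files are also read natively (`parseClstr()`).
3. **Cluster curation** (`runCuration()`) — for every cluster, check
   whether one species accounts for *strictly more than 90%* of the
   informative members. If not, escalate to genus, then family,
   re-ranking the tally at each step. A cluster resolving at genus emits
   `species = NA`; at family, `genus = NA` and `species = NA`; a cluster
   failing at family level is discarded and logged with every member's
   full lineage for manual review. Representatives not belonging to the
   dominant taxon are replaced by the longest member that does, and
   clusters with more than two species are highlighted. The reviewed
   warning lists feed an exclusion list for a second
   filter → cluster → curate pass.

A deterministic generator (`generateSequences()`) produces
taxonomy-structured fixtures — hierarchical divergence, planted
mislabels, planted header keywords — so the whole pipeline is testable
offline.

## Worked example

```r
library(refclust)

# 60 synthetic species (4 families x 5 genera x 3 species), 6 sequences
# each, with 2% of records deliberately mislabeled
fx  <- generateSequences(fixtureConfig(mislabelRate = 0.02, seed = 42))
cl  <- greedyCluster(fx$records, identity = 0.99)
cl
#> ClusterSet with 69 clusters covering 360 sequences
#>   cluster sizes: min 1, median 6, max 6; 7 singletons

cur <- runCuration(cl, fx$taxonomy, fx$records)
cur$report
#> CurationReport over 69 clusters
#>    family=2 genus=0 species=63 discarded=4 multi_species=6 gt2_species=1 rep_replaced=0 higher_rank_conflict=0
```

63 of 69 clusters carry a clean >90% species majority and keep their
species label. The planted mislabels make six clusters multi-species;
in these 6-member clusters one wrong label caps dominance at 5/6 ≈ 83%,
so none can resolve at species level: two recover at family level
(the wrong label came from a sister genus; they are emitted with
`genus = NA`, `species = NA`) and four fail at every rank and are
discarded into the log — exactly the manual-review queue the method is
designed to produce. `cur$records` and `cur$taxonomy` hold the curated
FASTA records and their QIIME-style two-column taxonomy
(`writeTaxonomyMap()`, with an optional Greengenes-prefix flag for
QIIME 2 import).

The same flow, file-to-file with a run summary and config snapshot:

```r
runPipeline(pipelineConfig("in.fasta", "in.tax.tsv", "outdir",
                           exclusionPath = "reviewed.txt"))  # 2nd pass
```

or from a shell via the thin CLI in `inst/scripts/refclust.R`
(`simulate | filter | cluster | curate | pipeline` subcommands).

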
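---
title: "Curating DNA barcode reference databases with refclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating DNA barcode reference databases with refclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refclust)
```

## The model

A barcode reference database maps sequences to trusted lineages. Two
failure modes dominate when the raw material comes from a public
archive: redundancy (many near-identical deposits per well-studied
species) and label error (sequences deposited under the wrong taxon,
e.g. fungal ITS amplified from plant tissue and submitted under the
host plant's name). Redundancy is removed by greedy clustering at high
identity; label error is then attacked *through* the clusters: sequences
that cluster together at 99% identity should nearly always be conspecific,
so a cluster whose members disagree on the species is itself evidence that
some labels are wrong.

The curation rule is a strict dominance check with rank escalation. For a
cluster with $n$ members informative at a rank (i.e. not `NA` there), let
$c$ be the count of the most frequent taxon. The cluster *resolves* at
that rank iff

$$ c / n > \theta, \qquad \theta = 0.9 . $$

The check runs species → genus → family. The first resolving rank labels
the cluster: ranks finer than it are blanked to `NA` in the output
taxonomy, and the representative sequence is re-selected so that it
belongs to the dominant taxon (the longest such member; the clustering
round's longest-overall choice is overridden when it is a minority
member — precisely the case where a mislabeled long sequence would
otherwise become the reference). A cluster failing even at family level
is discarded, and its members' full lineages go to a log for manual
review. Clusters with more than two distinct species are additionally
highlighted. The intended protocol is two-pass: curate, review the
warning/discard log by hand, collect confirmed mislabels in an exclusion
list, then re-filter, re-cluster and re-curate the cleaned input.

## Parameters that matter

* **Identity threshold** (`identity`, default 0.99). The clustering
  radius. Identity follows the CD-HIT global convention: optimal global
  alignment, identical columns divided by the *shorter* sequence length.
  This differs from BLAST-style local identity and makes a perfect
  sub-match count as identity 1, which suits partial barcode deposits.
* **Dominance threshold** (`dominance`, default 0.9, strict `>`). The
  strictness is deliberate and follows the "more than 90%" reading:
  9/10 and 18/20 escalate; 10/11 and 19/21 resolve. Because dominance
  must exceed 1/2, the dominant taxon is always unique.
* **Rank ladder** (`rankLadder`, default species, genus, family). A
  contiguous fine-to-coarse suffix of the six-rank lineage
  (phylum, class, order, family, genus, species).
* **Minimum length** (`minLength`, default 150 nt, strict `<` removal)
  and the **header keyword list** (`defaultKeywords()`): the record-level
  screens applied before clustering.
* **Alignment scores** (match +1, mismatch −1, gap −2, linear). These
  follow common nucleotide-clustering practice; identity is insensitive
  to moderate changes because near-threshold pairs are nearly gap-free.

## Numerical and design choices

* **NA handling in tallies.** Members with `NA` at the evaluated rank are
  excluded from numerator *and* denominator, and a rank with zero
  informative members fails and escalates. Absence of annotation is not
  treated as evidence of heterogeneity. This is an interpretation — the
  alternative (counting NA members in the denominator) would make poorly
  annotated clusters harder to keep.
* **Representative re-selection.** The replacement is the longest member
  of the dominant *taxon*, ties broken by accession (ascending). In a
  dereplicated database each sequence occurs once, so "most frequent" is
  read at the taxon level, with CD-HIT's own longest-sequence convention
  applied within the taxon.
* **Higher ranks of a backed-off cluster.** A genus- or family-resolved
  cluster takes its coarser ranks from the representative alone, not from
  a per-rank majority vote, to avoid chimeric lineages assembled from
  different members; a member disagreeing at a coarser rank raises the
  `higher_rank_conflict` flag instead.
* **Tie-breaking in the aligner.** When several global alignments tie on
  score, identity is the *maximum* identical-column count over the
  score-optimal alignments (computed by a second dynamic program over the
  optimal-path graph), so identity is a deterministic function of the
  pair.
* **Clustering order.** Length descending, ties by accession ascending;
  first-fit against representatives in creation order. Cluster output is
  therefore byte-reproducible. Equivalence with the CD-HIT binary's own
  internal tie-breaking is *not* claimed; the convention (longest-first
  greedy incremental, longest representative, shorter-sequence identity)
  is.
* **Strict parsers.** All readers abort on duplicate accessions, bodiless
  FASTA headers, over-long lineages and malformed `.clstr` clusters; a
  `lenient = TRUE` flag downgrades these to warnings and drops the
  offending entries, which GenBank-derived inputs sometimes require.
  Taxonomy lines with fewer than six ranks are right-padded with `NA`
  under a warning. Accessions containing the literal `...` are
  unsupported in `.clstr` files (the accession field ends at `...`, as
  CD-HIT emits it).

## What the synthetic generator emulates — and what it does not

`generateSequences()` evolves sequences down a systematic taxonomy: a
random family ancestor, genus ancestors at 12% substitutions/site from
it, species consensus sequences at 5% from the genus ancestor, and
individual records at 0.2% from the species consensus. Expected
within-species identity is then ≈ 99.6% (above the 99% clustering
radius) and between-genus identity well below 95%, reproducing the
separation the 99%/90% thresholds assume. Mislabels are planted by
swapping a record's *emitted* lineage for another species' while the
returned `truth` map keeps reality; header keywords are planted into
descriptions. Substitutions only — no indels — so identity arithmetic
stays analyzable; real ITS data additionally contains indels, length
variation between taxa, chimeras, and taxa whose marker simply cannot
separate species. Passing tests on this generator therefore demonstrate
the *algorithmic* contract (thresholds, escalation, representative
re-selection, determinism), not classification accuracy on real ITS
databases.

Default problem sizes were chosen as the smallest that exercise every
code path with headroom: the standard benchmark is 4 families × 5
genera × 3 species × 6 sequences (360 records, 60 species, 300 nt),
clustered and curated in well under two minutes on one CPU; oracle
comparisons for the aligner run on 200 random pairs of length ≤ 10
against an independent plain-R dynamic program and on shorter pairs
against full alignment enumeration.

## Degenerate inputs and edge behaviour

Empty FASTA files read as empty record sets and write back as empty
files. A cluster whose members are all `NA` at every ladder rank is
discarded (no rank can resolve). Clusters of size one resolve trivially
at species level when annotated. With equal-length candidates the
representative tie falls to the lexicographically smaller accession.
Small clusters interact visibly with the strict threshold: a 6-member
cluster with one wrong label has dominance 5/6 ≈ 83% and cannot resolve
at species level — on real data, where common species form large
clusters, the same single mislabel would be outvoted. This sensitivity
of small clusters is inherent to the member-fraction rule, and it is the
reason discarded clusters are logged rather than silently dropped.

## Known limitations

* O(n × clusters) alignments per clustering round: fine for reference
  curation at desk scale, not a CD-HIT replacement for millions of
  reads. Pre-computed `.clstr` files can be supplied instead.
* The six-rank lineage (phylum … species) is fixed; sub-species ranks
  and rank-free taxonomies are out of scope.
* Cross-kingdom contaminant *detection* (similarity screens against
  curated fungal databases, LCA screening) is upstream manual work; this
  package consumes its outcome as an exclusion list.
* The strict greater-than at exactly 90% and the NA-exclusion rule are
  the package's committed readings of an ambiguous convention; both are
  centralized (`dominance`, `tallyComposition()`) should a user need the
  alternative.
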
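#' Tally a cluster's taxonomic composition at one rank
#'
#' Counts members by their taxon name at `rank`, excluding members whose
#' lineage carries the NA token there: absence of annotation is treated
#' as no evidence, so NA members enter neither numerator nor denominator.
#' Each member counts once (presence, not abundance) — the input is a
#' sequence database, not a read set.
#'
#' @param members Character vector of member accessions.
#' @param taxmap A [TaxonomyMap-class] covering every member; a missing
#'   accession is an error (taxonomy must be attached before curation).
#' @param rank One of [taxonomyRanks()].
#' @return `list(counts=, nInformative=, nNA=)` with `counts` a named
#'   integer vector sorted by decreasing count (ties by name).
#' @export
tallyComposition <- function(members, taxmap, rank) {
  rank <- base::match.arg(rank, RANKS)
  i <- base::match(members, taxmap@table$accession)
  if (anyNA(i))
    stop(sprintf("member accession(s) missing from taxonomy map: %s",
                 paste(members[is.na(i)], collapse = ", ")))
  tax <- taxmap@table[[rank]][i]
  informative <- tax != NA_TOKEN
  counts <- table(tax[informative])
  counts <- setNames(as.integer(counts), names(counts))
  if (length(counts))
    counts <- counts[order(-counts, names(counts))]
  list(counts = counts, nInformative = sum(informative),
       nNA = sum(!informative))
}

#' Evaluate one cluster's taxonomic coherence
#'
#' Walks the rank ladder fine to coarse (default species, genus, family).
#' A rank resolves the cluster iff it has at least one informative member
#' and the most frequent taxon's share of informative members is
#' *strictly* greater than `dominance` ("more than 90%": a fraction of
#' exactly 0.9 escalates).  The first resolving rank wins.  A cluster no
#' rank resolves is discarded.  Flags record heterogeneity
#' (`multi_species` for >1 distinct non-NA species, `gt2_species` for
#' more than `flagSpeciesGt`) and representative replacement.
#'
#' @param clusterId Integer id (for reporting).
#' @param members Character vector of member accessions.
#' @param incomingRep Accession of the clustering-round representative.
#' @param taxmap A [TaxonomyMap-class].
#' @param records DNAStringSet for length lookup during representative
#'   re-selection.
#' @param dominance Dominance threshold in `(0, 1)`, strict (default 0.9).
#' @param rankLadder Ranks to try, fine to coarse; must be a contiguous
#'   run of [taxonomyRanks()] read backwards (default species, genus,
#'   family).
#' @param flagSpeciesGt Highlight clusters with more than this many
#'   distinct species (default 2).
#' @return A [ClusterDecision-class].
#' @export
evaluateCluster <- function(clusterId, members, incomingRep, taxmap,
                            records, dominance = 0.9,
                            rankLadder = c("species", "genus", "family"),
                            flagSpeciesGt = 2L) {
  stopifnot(dominance > 0, dominance < 1, length(rankLadder) >= 1)
  if (!all(rankLadder %in% RANKS)) stop("unknown rank in ladder")
  if (is.unsorted(rev(base::match(rankLadder, RANKS))))
    stop("rankLadder must run fine to coarse")

  tallies <- list()
  resolved <- "discarded"
  dominant <- NA_character_
  for (rank in rankLadder) {
    t <- tallyComposition(members, taxmap, rank)
    tallies[[rank]] <- t$counts
    if (t$nInformative > 0 &&
        t$counts[1] / t$nInformative > dominance) {
      resolved <- rank
      dominant <- names(t$counts)[1]
      break
    }
  }

  sp <- tallyComposition(members, taxmap, "species")$counts
  flags <- character()
  if (length(sp) > 1L) flags <- c(flags, "multi_species")
  if (length(sp) > flagSpeciesGt) flags <- c(flags, "gt2_species")

  representative <- NA_character_
  if (resolved != "discarded") {
    representative <- selectRepresentative(members, incomingRep, taxmap,
                                           records, resolved, dominant)
    if (!identical(representative, incomingRep))
      flags <- c(flags, "rep_replaced")
  }
  new("ClusterDecision", clusterId = as.integer(clusterId),
      resolvedRank = resolved, dominantTaxon = dominant,
      representative = representative, flags = flags, tallies = tallies)
}

#' Select a cluster's representative from the dominant taxon
#'
#' The incoming (longest-sequence) representative is kept iff its lineage
#' at the resolved rank equals the dominant taxon; otherwise it is
#' replaced by the longest member belonging to the dominant taxon (ties
#' broken by accession, ascending) so the emitted reference sequence
#' always carries the taxon the cluster is labeled with.
#'
#' @param members Character vector of member accessions.
#' @param incomingRep Incoming representative accession.
#' @param taxmap A [TaxonomyMap-class].
#' @param records DNAStringSet for length lookup.
#' @param resolvedRank Rank the cluster resolved at.
#' @param dominantTaxon Dominant taxon name at that rank.
#' @return The selected accession, always one of `members`.
#' @export
selectRepresentative <- function(members, incomingRep, taxmap, records,
                                 resolvedRank, dominantTaxon) {
  i <- base::match(members, taxmap@table$accession)
  tax <- taxmap@table[[resolvedRank]][i]
  if (incomingRep %in% members &&
      tax[base::match(incomingRep, members)] == dominantTaxon)
    return(incomingRep)
  cand <- members[tax == dominantTaxon]
  if (!length(cand))
    stop(sprintf(
      "internal inconsistency: no member of cluster carries taxon '%s'",
      dominantTaxon))
  w <- width(records)[base::match(cand, names(records))]
  if (anyNA(w))
    stop(sprintf("no sequence record for member(s): %s",
                 paste(cand[is.na(w)], collapse = ", ")))
  cand[order(-w, cand, method = "radix")][1]
}

#' Build the output lineage for a resolved cluster
#'
#' Starts from the representative's lineage and blanks every rank
#' strictly finer than the resolved rank to NA (a genus-resolved cluster
#' emits species = NA; family-resolved emits genus = NA and species =
#' NA).  Ranks at and above the resolved rank are taken from the
#' representative alone — no majority vote — to avoid chimeric
#' lineages; if any member disagrees (non-NA) with the representative at
#' a coarser rank, the `higher_rank_conflict` flag is raised but the
#' representative's lineage is still emitted.
#'
#' @param decision A resolved [ClusterDecision-class].
#' @param members Character vector of the cluster's member accessions.
#' @param taxmap A [TaxonomyMap-class].
#' @return `list(lineage=, conflict=)`: the six-rank character vector and
#'   whether a coarser-rank conflict was seen.
#' @export
buildOutputTaxonomy <- function(decision, members, taxmap) {
  if (decision@resolvedRank == "discarded")
    stop("cannot build output taxonomy for a discarded cluster")
  lin <- lineageOf(taxmap, decision@representative)
  ri <- base::match(decision@resolvedRank, RANKS)
  if (ri < length(RANKS))
    lin[(ri + 1L):length(RANKS)] <- NA_TOKEN
  conflict <- FALSE
  if (ri > 1L) {
    idx <- base::match(members, taxmap@table$accession)
    for (r in RANKS[seq_len(ri - 1L)]) {
      v <- taxmap@table[[r]][idx]
      v <- v[v != NA_TOKEN]
      if (length(v) && any(v != lin[[r]])) { conflict <- TRUE; break }
    }
  }
  list(lineage = lin, conflict = conflict)
}

#' Curate a full clustering round
#'
#' Applies [evaluateCluster()] to every cluster, re-selects
#' representatives, builds output lineages with NA backoff, and
#' assembles the curated FASTA-ready records, the curated taxonomy map
#' (one line per kept cluster, keyed by the possibly-replaced
#' representative), and a [CurationReport-class] carrying decisions,
#' aggregate counts, and the per-member lineage detail of discarded and
#' highlighted clusters.  The whole step is deterministic.
#'
#' @param clusters A [ClusterSet-class].
#' @param taxmap A [TaxonomyMap-class] covering every member.
#' @param records DNAStringSet covering every member.
#' @param dominance,rankLadder,flagSpeciesGt See [evaluateCluster()].
#' @return `list(records=, taxonomy=, report=)`.
#' @export
runCuration <- function(clusters, taxmap, records, dominance = 0.9,
                        rankLadder = c("species", "genus", "family"),
                        flagSpeciesGt = 2L) {
  n <- length(clusters)
  rows <- vector("list", n)
  out_acc <- character(); out_lin <- list()
  discarded_detail <- list(); flagged_detail <- list()

  member_detail <- function(members) {
    i <- base::match(members, taxmap@table$accession)
    data.frame(accession = members, taxmap@table[i, RANKS, drop = FALSE],
               stringsAsFactors = FALSE, row.names = NULL)
  }

  for (k in seq_len(n)) {
    cid <- clusters@ids[k]
    members <- clusters@members[[k]]
    dec <- evaluateCluster(cid, members, clusters@representatives[k],
                           taxmap, records, dominance, rankLadder,
                           flagSpeciesGt)
    flags <- dec@flags
    if (dec@resolvedRank != "discarded") {
      ot <- buildOutputTaxonomy(dec, members, taxmap)
      if (ot$conflict) {
        flags <- c(flags, "higher_rank_conflict")
        dec@flags <- flags
      }
      out_acc <- c(out_acc, dec@representative)
      out_lin <- c(out_lin, list(ot$lineage))
    } else {
      discarded_detail[[as.character(cid)]] <- member_detail(members)
    }
    if ("gt2_species" %in% flags)
      flagged_detail[[as.character(cid)]] <- member_detail(members)
    sp <- dec@tallies[["species"]]
    rows[[k]] <- data.frame(
      cluster_id = cid, resolved_rank = dec@resolvedRank,
      dominant_taxon = dec@dominantTaxon,
      representative = dec@representative,
      flags = paste(flags, collapse = ","),
      n_members = length(members),
      n_species = if (is.null(sp)) NA_integer_ else length(sp),
      stringsAsFactors = FALSE)
  }
  dtab <- do.call(rbind, rows)
  if (is.null(dtab))
    dtab <- data.frame(cluster_id = integer(), resolved_rank = character(),
                       dominant_taxon = character(),
                       representative = character(), flags = character(),
                       n_members = integer(), n_species = integer(),
                       stringsAsFactors = FALSE)
  report <- new("CurationReport", decisions = dtab,
                counts = recountDecisions(dtab),
                discardedDetail = discarded_detail,
                flaggedDetail = flagged_detail)

  out_records <- records[base::match(out_acc, names(records))]
  out_tax <- TaxonomyMap(out_acc,
                         if (length(out_lin)) do.call(rbind, out_lin)
                         else matrix(character(), 0, 6))
  list(records = out_records, taxonomy = out_tax, report = report)
}
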
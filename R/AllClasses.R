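#' TaxonomyMap: accession -> six-rank lineage
#'
#' A mapping from sequence accessions to ordered six-rank lineages
#' (Phylum, Class, Order, Family, Genus, Species).  Unassigned ranks carry
#' the literal token `"NA"`.  Accessions are unique; looking up an absent
#' accession is an error, never a silent all-NA lineage.
#'
#' @slot table data.frame with columns `accession` plus the six ranks,
#'   all character, one row per accession.
#' @export
setClass("TaxonomyMap", representation(table = "data.frame"))

setValidity("TaxonomyMap", function(object) {
  tab <- object@table
  need <- c("accession", RANKS)
  if (!identical(colnames(tab), need))
    return(sprintf("table columns must be exactly: %s",
                   paste(need, collapse = ", ")))
  if (!all(vapply(tab, is.character, logical(1))))
    return("all columns must be character")
  if (anyDuplicated(tab$accession))
    return(sprintf("duplicate accessions: %s",
                   paste(unique(tab$accession[duplicated(tab$accession)]),
                         collapse = ", ")))
  if (any(!nzchar(tab$accession)) || any(grepl("\\s", tab$accession)))
    return("accessions must be non-empty and free of whitespace")
  rk <- as.matrix(tab[RANKS])
  if (any(is.na(rk)) || any(!nzchar(rk)))
    return("rank names must be non-empty strings; use the token \"NA\"")
  TRUE
})

#' Construct a TaxonomyMap
#'
#' @param accession Character vector of unique accession tokens.
#' @param lineages Character matrix or data.frame with six columns in rank
#'   order (phylum..species), one row per accession; empty strings and `NA`
#'   values become the `"NA"` token.
#' @return A [TaxonomyMap-class] object.
#' @export
#' @examples
#' TaxonomyMap("A1", rbind(c("Streptophyta", "Magnoliopsida", "Fagales",
#'   "Betulaceae", "Corylus", "Corylus avellana")))
TaxonomyMap <- function(accession = character(),
                        lineages = matrix(character(), 0, 6)) {
  lineages <- as.matrix(lineages)
  if (length(accession) == 0L && nrow(lineages) == 0L) {
    tab <- data.frame(accession = character(),
                      matrix(character(), 0, 6,
                             dimnames = list(NULL, RANKS)),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(lineages) != 6L)
      stop("lineages must have exactly six columns (phylum..species)")
    if (nrow(lineages) != length(accession))
      stop("one lineage row per accession required")
    mode(lineages) <- "character"
    lineages[is.na(lineages) | !nzchar(lineages)] <- NA_TOKEN
    colnames(lineages) <- RANKS
    tab <- data.frame(accession = as.character(accession), lineages,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  new("TaxonomyMap", table = tab)
}

#' ClusterSet: one clustering round's clusters
#'
#' Each cluster has an integer id (creation order), a representative
#' accession, an ordered member list containing the representative, and the
#' identity of each member to the representative (`NA` for the
#' representative itself when identities were not computed, e.g. after
#' parsing a `.clstr` file without percentages).
#'
#' @slot ids integer cluster ids, `>= 0`, in file/creation order.
#' @slot representatives character, one accession per cluster.
#' @slot members CharacterList, ordered member accessions per cluster.
#' @slot identities NumericList parallel to `members`; fraction identity of
#'   each member to its representative (`NA_real_` where unknown; the
#'   representative's own entry is 1).
#' @export
setClass("ClusterSet",
         representation(ids = "integer",
                        representatives = "character",
                        members = "CharacterList",
                        identities = "NumericList"))

setValidity("ClusterSet", function(object) {
  n <- length(object@ids)
  if (length(object@representatives) != n ||
      length(object@members) != n || length(object@identities) != n)
    return("slot lengths disagree")
  if (n == 0L) return(TRUE)
  if (any(object@ids < 0L)) return("cluster ids must be >= 0")
  for (i in seq_len(n)) {
    mem <- object@members[[i]]
    if (length(mem) == 0L)
      return(sprintf("cluster %d has no members", object@ids[i]))
    if (anyDuplicated(mem))
      return(sprintf("cluster %d has duplicate members", object@ids[i]))
    if (!(object@representatives[i] %in% mem))
      return(sprintf("cluster %d: representative not among members",
                     object@ids[i]))
    if (length(object@identities[[i]]) != length(mem))
      return(sprintf("cluster %d: identities not parallel to members",
                     object@ids[i]))
  }
  allmem <- unlist(object@members)
  if (anyDuplicated(allmem))
    return("an accession appears in more than one cluster")
  TRUE
})

#' Construct a ClusterSet
#'
#' @param ids Integer cluster ids (creation/file order).
#' @param representatives Character accessions, one per cluster.
#' @param members CharacterList of member accessions per cluster.
#' @param identities Optional NumericList of member identities to the
#'   representative; defaults to all-`NA`.
#' @return A [ClusterSet-class].
#' @export
clusterSet <- function(ids = integer(), representatives = character(),
                       members = CharacterList(),
                       identities = NULL) {
  if (is.null(identities)) {
    identities <- NumericList(lapply(members, function(m) {
      rep(NA_real_, length(m))
    }))
  }
  new("ClusterSet", ids = as.integer(ids),
      representatives = representatives,
      members = members, identities = identities)
}

#' ClusterDecision: the curation verdict for one cluster
#'
#' @slot clusterId integer id of the evaluated cluster.
#' @slot resolvedRank one of `"species"`, `"genus"`, `"family"`,
#'   `"discarded"` (more generally: a rank of the configured ladder).
#' @slot dominantTaxon name of the dominant taxon at the resolved rank;
#'   `NA_character_` when discarded.
#' @slot representative accession of the (possibly replaced) representative;
#'   `NA_character_` when discarded.
#' @slot flags character subset of `multi_species`, `gt2_species`,
#'   `rep_replaced`, `higher_rank_conflict`.
#' @slot tallies named list of per-rank taxon->count tables actually
#'   computed while walking the rank ladder.
#' @export
setClass("ClusterDecision",
         representation(clusterId = "integer",
                        resolvedRank = "character",
                        dominantTaxon = "character",
                        representative = "character",
                        flags = "character",
                        tallies = "list"))

setValidity("ClusterDecision", function(object) {
  ok_flags <- c("multi_species", "gt2_species", "rep_replaced",
                "higher_rank_conflict")
  if (!all(object@flags %in% ok_flags))
    return(sprintf("unknown flags: %s",
                   paste(setdiff(object@flags, ok_flags), collapse = ", ")))
  if (object@resolvedRank != "discarded") {
    if (is.na(object@dominantTaxon) || is.na(object@representative))
      return("resolved clusters need a dominant taxon and a representative")
  }
  TRUE
})

#' CurationReport: aggregate curation outcome
#'
#' @slot decisions data.frame, one row per cluster: `cluster_id`,
#'   `resolved_rank`, `dominant_taxon`, `representative`, `flags`
#'   (comma-joined), `n_members`, `n_species` (distinct non-NA species).
#' @slot counts named integer vector: clusters resolved per ladder rank,
#'   `discarded`, and flag tallies.
#' @slot discardedDetail named list (by cluster id) of data.frames with
#'   member accession + six-rank lineage for every discarded cluster.
#' @slot flaggedDetail same structure for clusters flagged with more
#'   species than the configured highlight threshold.
#' @export
setClass("CurationReport",
         representation(decisions = "data.frame",
                        counts = "integer",
                        discardedDetail = "list",
                        flaggedDetail = "list"))

setValidity("CurationReport", function(object) {
  d <- object@decisions
  need <- c("cluster_id", "resolved_rank", "dominant_taxon",
            "representative", "flags", "n_members", "n_species")
  if (!all(need %in% colnames(d)))
    return(sprintf("decisions must have columns: %s",
                   paste(need, collapse = ", ")))
  # counts must be recomputable from decisions
  rec <- recountDecisions(d)
  if (!identical(rec[names(object@counts)], object@counts))
    return("counts are inconsistent with decisions")
  if (length(object@discardedDetail) !=
      sum(d$resolved_rank == "discarded"))
    return("discardedDetail length disagrees with discarded decisions")
  TRUE
})

# tally a decisions table into the counts vector; used by the validity
# method so stored counts can never drift from the decisions they summarize
recountDecisions <- function(d) {
  ranks <- c(RANKS, "discarded")
  byrank <- vapply(ranks, function(r) sum(d$resolved_rank == r), integer(1))
  byrank <- byrank[byrank > 0 | names(byrank) %in%
                     c("species", "genus", "family", "discarded")]
  fl <- strsplit(d$flags, ",", fixed = TRUE)
  flagn <- vapply(c("multi_species", "gt2_species", "rep_replaced",
                    "higher_rank_conflict"),
                  function(f) sum(vapply(fl, function(x) f %in% x,
                                         logical(1))),
                  integer(1))
  c(byrank, flagn)
}
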
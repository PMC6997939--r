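#' @export
setGeneric("accessions", function(x, ...) standardGeneric("accessions"))

#' @export
setGeneric("lineages", function(x, ...) standardGeneric("lineages"))

#' @export
setGeneric("lineageOf", function(x, accession, ...)
  standardGeneric("lineageOf"))

#' @export
setGeneric("representatives", function(x, ...)
  standardGeneric("representatives"))

#' @export
setGeneric("clusterMembers", function(x, ...)
  standardGeneric("clusterMembers"))

#' @export
setGeneric("clusterIds", function(x, ...) standardGeneric("clusterIds"))

#' @export
setGeneric("decisions", function(x, ...) standardGeneric("decisions"))

#' @export
setGeneric("curationCounts", function(x, ...)
  standardGeneric("curationCounts"))

#' Accessions of a TaxonomyMap
#' @param x A [TaxonomyMap-class].
#' @param ... Unused.
#' @return Character vector of accessions.
#' @export
setMethod("accessions", "TaxonomyMap", function(x, ...) x@table$accession)

#' Lineage table of a TaxonomyMap
#' @param x A [TaxonomyMap-class].
#' @param ... Unused.
#' @return data.frame of accession + six rank columns.
#' @export
setMethod("lineages", "TaxonomyMap", function(x, ...) x@table)

#' Look up one accession's lineage
#' @param x A [TaxonomyMap-class].
#' @param accession Single accession token.
#' @param ... Unused.
#' @return Named character vector of the six ranks.
#' @export
setMethod("lineageOf", "TaxonomyMap", function(x, accession, ...) {
  i <- match(accession, x@table$accession)
  if (is.na(i))
    stop(sprintf("accession '%s' not found in taxonomy map", accession))
  unlist(x@table[i, RANKS])
})

#' @export
setMethod("length", "TaxonomyMap", function(x) nrow(x@table))

setMethod("show", "TaxonomyMap", function(object) {
  cat(sprintf("TaxonomyMap with %d accessions (%d ranks: %s)\n",
              nrow(object@table), length(RANKS),
              paste(RANKS, collapse = ", ")))
  na_per_rank <- vapply(object@table[RANKS],
                        function(v) sum(v == NA_TOKEN), integer(1))
  cat("  NA per rank:", paste(sprintf("%s=%d", names(na_per_rank),
                                      na_per_rank), collapse = " "), "\n")
})

#' @export
setMethod("length", "ClusterSet", function(x) length(x@ids))

#' Representative accessions of a ClusterSet
#' @param x A [ClusterSet-class].
#' @param ... Unused.
#' @return Character vector, one accession per cluster.
#' @export
setMethod("representatives", "ClusterSet", function(x, ...)
  x@representatives)

#' Member accessions of a ClusterSet
#' @param x A [ClusterSet-class].
#' @param ... Unused.
#' @return CharacterList of member accessions per cluster.
#' @export
setMethod("clusterMembers", "ClusterSet", function(x, ...) x@members)

#' Cluster ids of a ClusterSet
#' @param x A [ClusterSet-class].
#' @param ... Unused.
#' @return Integer vector of ids in creation order.
#' @export
setMethod("clusterIds", "ClusterSet", function(x, ...) x@ids)

setMethod("show", "ClusterSet", function(object) {
  sizes <- lengths(object@members)
  cat(sprintf("ClusterSet with %d clusters covering %d sequences\n",
              length(object@ids), sum(sizes)))
  if (length(sizes))
    cat(sprintf("  cluster sizes: min %d, median %g, max %d; %d singletons\n",
                min(sizes), stats::median(sizes), max(sizes),
                sum(sizes == 1L)))
})

setMethod("show", "ClusterDecision", function(object) {
  cat(sprintf("ClusterDecision for cluster %d: %s", object@clusterId,
              object@resolvedRank))
  if (object@resolvedRank != "discarded")
    cat(sprintf(" ('%s', representative %s)", object@dominantTaxon,
                object@representative))
  cat("\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Per-cluster decision table of a CurationReport
#' @param x A [CurationReport-class].
#' @param ... Unused.
#' @return data.frame with one row per cluster.
#' @export
setMethod("decisions", "CurationReport", function(x, ...) x@decisions)

#' Aggregate counts of a CurationReport
#' @param x A [CurationReport-class].
#' @param ... Unused.
#' @return Named integer vector (per-rank resolutions, discards, flags).
#' @export
setMethod("curationCounts", "CurationReport", function(x, ...) x@counts)

setMethod("show", "CurationReport", function(object) {
  cat(sprintf("CurationReport over %d clusters\n", nrow(object@decisions)))
  cnt <- object@counts
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
})
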
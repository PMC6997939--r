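#' Write the plain-text discard / warning log
#'
#' One block per discarded cluster (cluster id, then one line per member
#' with accession and full six-rank lineage), followed by a section
#' listing clusters highlighted for containing more species than the
#' configured threshold, with the same per-member detail.
#'
#' @param report A [CurationReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDiscardLog <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_detail <- function(det) {
    for (cid in names(det)) {
      writeLines(sprintf("Cluster %s", cid), con)
      d <- det[[cid]]
      writeLines(sprintf("  %s\t%s", d$accession,
                         apply(as.matrix(d[RANKS]), 1, paste,
                               collapse = ";")), con)
    }
  }
  writeLines("# Discarded clusters (failed dominance at every rank)", con)
  nd <- length(report@discardedDetail)
  writeLines(sprintf("%d clusters discarded", nd), con)
  fmt_detail(report@discardedDetail)
  writeLines("", con)
  writeLines("# Clusters flagged: more than 2 species", con)
  writeLines(sprintf("%d clusters flagged", length(report@flaggedDetail)),
             con)
  fmt_detail(report@flaggedDetail)
  invisible(path)
}

#' Write the per-cluster decision table as TSV
#'
#' @param report A [CurationReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReportTsv <- function(report, path) {
  write.table(report@decisions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a stage-by-stage record-count summary as TSV
#'
#' @param summary data.frame with columns `stage`, `n_in`, `n_removed`,
#'   `n_out` as produced by [runPipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
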
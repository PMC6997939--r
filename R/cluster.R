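#' Greedy incremental clustering at an identity threshold
#'
#' Self-contained reimplementation of the CD-HIT clustering convention,
#' so that the full curation pipeline runs without external binaries.
#' Records are processed by decreasing length (ties by accession,
#' ascending); each record joins the earliest-created cluster whose
#' representative has [pairwiseIdentity()] `>= identity` with it,
#' otherwise it founds a new cluster with itself as representative.
#' Because founders are processed longest-first, every representative is
#' the longest member of its cluster, and any two representatives have
#' identity below the threshold.
#'
#' This is a convention-level reimplementation, not a performance clone:
#' there is no short-word prefilter, so cost is O(n x clusters)
#' alignments, acceptable at reference-curation scale.
#'
#' @param records DNAStringSet with unique accession names.
#' @param identity Identity threshold in `(0, 1]` (default 0.99).
#' @param bothStrands Also test the reverse complement (default `FALSE`;
#'   inputs are normally orientation-normalized barcode regions).
#' @param match,mismatch,gap Alignment scoring, see [pairwiseIdentity()].
#' @return A [ClusterSet-class]; cluster ids follow creation order and
#'   each member carries its identity to the representative.
#' @export
greedyCluster <- function(records, identity = 0.99, bothStrands = FALSE,
                          match = 1, mismatch = -1, gap = -2) {
  stopifnot(identity > 0, identity <= 1)
  if (!length(records))
    return(clusterSet(integer(), character(), CharacterList()))
  ord <- order(-width(records), names(records), method = "radix")
  seqs <- as.character(records)[ord]
  accs <- names(records)[ord]

  rep_seq <- character(); rep_acc <- character()
  members <- list(); idents <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(rep_seq)) {
      idn <- pairwiseIdentity(seqs[i], rep_seq[k], match, mismatch, gap,
                              bothStrands)
      if (idn >= identity) {
        members[[k]] <- c(members[[k]], accs[i])
        idents[[k]] <- c(idents[[k]], idn)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, seqs[i])
      rep_acc <- c(rep_acc, accs[i])
      members[[length(rep_seq)]] <- accs[i]
      idents[[length(rep_seq)]] <- 1
    }
  }
  clusterSet(seq_along(rep_acc) - 1L, rep_acc,
             CharacterList(members), NumericList(idents))
}
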
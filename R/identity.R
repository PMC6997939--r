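#' Pairwise identity under the CD-HIT convention
#'
#' Computes an optimal global (Needleman-Wunsch) alignment under linear
#' gap costs and returns identity = identical aligned columns / length of
#' the shorter sequence.  This is CD-HIT's global-identity convention and
#' differs from BLAST-style local identity: a perfect sub-match of a short
#' sequence inside a long one scores identity 1.  When several alignments
#' tie on score, the maximum identical-column count over the score-optimal
#' alignments is used, which makes the value deterministic.  IUPAC
#' ambiguity codes only match themselves.
#'
#' @param a,b Character strings or length-1 DNAStringSet/DNAString
#'   elements; non-empty.
#' @param match,mismatch,gap Alignment scores (defaults +1, -1, -2;
#'   linear gap penalty per gap column).
#' @param bothStrands If `TRUE`, also align `a` against the reverse
#'   complement of `b` and return the larger identity.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")      # 0.75
#' pairwiseIdentity("ACGTACGT", "ACGT")  # 1: shorter-sequence denominator
pairwiseIdentity <- function(a, b, match = 1, mismatch = -1, gap = -2,
                             bothStrands = FALSE) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  denom <- min(nchar(a), nchar(b))
  fwd <- .nwAlign(a, b, match, mismatch, gap)$matches / denom
  if (!bothStrands) return(fwd)
  brc <- as.character(reverseComplement(DNAStringSet(b))[[1]])
  max(fwd, .nwAlign(a, brc, match, mismatch, gap)$matches / denom)
}

#' Optimal global alignment score and match count
#'
#' Lower-level access to the aligner behind [pairwiseIdentity()]: the
#' optimal Needleman-Wunsch score and the maximum number of identical
#' columns among score-optimal alignments.
#'
#' @inheritParams pairwiseIdentity
#' @return `list(score=, matches=)`.
#' @export
alignmentScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .nwAlign(a, b, match, mismatch, gap)
}
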
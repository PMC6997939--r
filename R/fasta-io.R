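#' Build a set of sequence records
#'
#' Sequence records travel through the package as a
#' [Biostrings::DNAStringSet] whose names are the accessions and whose
#' `mcols()$description` carries the free-text header remainder.
#' Sequences are uppercased and `U` is normalized to `T`; characters must
#' belong to the IUPAC nucleotide alphabet.
#'
#' @param sequences Character vector of sequences (or a DNAStringSet).
#' @param accessions Character vector of unique, whitespace-free tokens.
#' @param descriptions Character vector of free text (may be empty strings).
#' @return A DNAStringSet with accession names and a `description` mcol.
#' @export
#' @examples
#' r <- seqRecords(c("acgu", "GGTT"), c("A1", "A2"), c("test", ""))
#' as.character(r[["A1"]])  # "ACGT"
seqRecords <- function(sequences, accessions,
                       descriptions = rep("", length(sequences))) {
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", sequences)
  if (any(bad))
    stop(sprintf("non-IUPAC characters in sequence(s): %s",
                 paste(accessions[bad], collapse = ", ")))
  if (any(!nzchar(sequences)))
    stop(sprintf("empty sequence for accession(s): %s",
                 paste(accessions[!nzchar(sequences)], collapse = ", ")))
  if (any(!nzchar(accessions)) || any(grepl("\\s", accessions)))
    stop("accessions must be non-empty and contain no whitespace")
  dup <- unique(accessions[duplicated(accessions)])
  if (length(dup))
    stop(sprintf("duplicate accession(s): %s", paste(dup, collapse = ", ")))
  x <- DNAStringSet(sequences)
  names(x) <- accessions
  mcols(x) <- DataFrame(description = as.character(descriptions))
  x
}

#' Descriptions of a record set
#'
#' @param x DNAStringSet as built by [seqRecords()] or [readFastaRecords()].
#' @return Character vector of descriptions ("" where absent).
#' @export
descriptions <- function(x) {
  d <- mcols(x)$description
  if (is.null(d)) rep("", length(x)) else as.character(d)
}

#' Read a FASTA file into sequence records
#'
#' The accession is the first whitespace-delimited token after `>`; the
#' description is the remainder of the header line.  Multi-line sequences
#' are joined, case is normalized to upper, and `U` becomes `T`.  Input
#' order is preserved.
#'
#' @param path FASTA file path.
#' @param lenient If `TRUE`, recoverable format errors (duplicate
#'   accessions, headers with no sequence body) are downgraded to warnings
#'   and the offending records dropped (first occurrence kept for
#'   duplicates).  Default `FALSE`: strict.
#' @return DNAStringSet with accession names and description mcol; empty
#'   file yields an empty set.
#' @export
readFastaRecords <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L)
    return(seqRecords(character(), character(), character()))
  raw <- readBStringSet(path)
  hdr <- names(raw)
  acc <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- as.character(raw)

  empty <- !nzchar(seqs)
  if (any(empty)) {
    msg <- sprintf("header(s) with no sequence body: %s",
                   paste(hdr[empty], collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg)
    acc <- acc[!empty]; desc <- desc[!empty]; seqs <- seqs[!empty]
  }
  dup <- duplicated(acc)
  if (any(dup)) {
    msg <- sprintf("duplicate accession(s): %s",
                   paste(unique(acc[dup]), collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg)
    acc <- acc[!dup]; desc <- desc[!dup]; seqs <- seqs[!dup]
  }
  seqRecords(seqs, acc, desc)
}

#' Write sequence records to FASTA
#'
#' Headers are `>ACC description`, or `>ACC` with no trailing space when
#' the description is empty, so that write/read round-trips are identical.
#'
#' @param records DNAStringSet from [seqRecords()]/[readFastaRecords()].
#' @param path Output path.
#' @param lineWidth Sequence line width in characters (default 80).
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(records, path, lineWidth = 80L) {
  stopifnot(lineWidth >= 1L)
  out <- records
  d <- descriptions(records)
  names(out) <- ifelse(nzchar(d), paste(names(records), d), names(records))
  writeXStringSet(out, filepath = path, width = lineWidth)
  invisible(path)
}
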
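#' Remove records whose description contains a flagged keyword
#'
#' GenBank definition lines carrying words like "predicted" or
#' "unverified" signal annotations that should not seed a reference
#' database.  A record is removed iff its description contains any
#' keyword as a case-insensitive substring (the accession itself is never
#' searched).  Note that substring matching is deliberate and
#' conservative: "protein" also removes "proteinase" records.
#'
#' @param records DNAStringSet with description mcol.
#' @param keywords Character vector of keywords; default
#'   [defaultKeywords()].
#' @return `list(kept=, removed=)`, a partition of the input with order
#'   preserved in each part.
#' @export
#' @examples
#' r <- seqRecords(c("ACGT", "ACGT"), c("A1", "A2"),
#'                 c("PREDICTED: Arabidopsis ITS1", "Corylus avellana ITS"))
#' filterHeaders(r)$removed  # A1 only
filterHeaders <- function(records, keywords = defaultKeywords()) {
  if (!length(keywords)) stop("keyword list must be non-empty")
  d <- tolower(descriptions(records))
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
    grepl(k, d, fixed = TRUE)), rep(FALSE, length(records)))
  list(kept = records[!hit], removed = records[hit])
}

#' Remove records shorter than a minimum length
#'
#' The boundary is strict: a record is removed iff its length is strictly
#' below `minLength`, so with the default of 150 a 150 nt sequence is
#' kept and a 149 nt one removed.
#'
#' @param records DNAStringSet.
#' @param minLength Minimum length in nt (default 150).
#' @return `list(kept=, removed=)` partition, order preserved.
#' @export
filterLength <- function(records, minLength = 150L) {
  stopifnot(minLength >= 1L)
  short <- width(records) < minLength
  list(kept = records[!short], removed = records[short])
}

#' Concatenate ITS1, 5.8S and ITS2 region records into full-ITS records
#'
#' Only accessions present in all three inputs are emitted; the sequence
#' is ITS1 + 5.8S + ITS2 in that order, the description is inherited from
#' the ITS1 record, and the output is sorted by accession.
#'
#' @param its1,s58,its2 DNAStringSets keyed by accession (each accession
#'   at most once per set).
#' @return DNAStringSet of concatenated records.
#' @export
concatenateITS <- function(its1, s58, its2) {
  common <- sort(Reduce(intersect, list(names(its1), names(s58),
                                        names(its2))))
  if (!length(common))
    return(seqRecords(character(), character(), character()))
  seqs <- paste0(as.character(its1[common]), as.character(s58[common]),
                 as.character(its2[common]))
  d1 <- setNames(descriptions(its1), names(its1))
  seqRecords(seqs, common, unname(d1[common]))
}

#' Remove records on an exclusion list
#'
#' Used for the second curation pass: accessions judged misidentified
#' after manual review of the warning log are dropped from the unclustered
#' input before re-clustering.  Listed accessions absent from the records
#' are reported via a warning attribute, not an error.
#'
#' @param records DNAStringSet.
#' @param accessionIds Character vector of accessions to remove.
#' @return `list(kept=, removed=, missing=)`: the partition plus the ids
#'   that matched nothing.
#' @export
applyExclusionList <- function(records, accessionIds) {
  accessionIds <- unique(as.character(accessionIds))
  hit <- names(records) %in% accessionIds
  missing <- setdiff(accessionIds, names(records))
  if (length(missing))
    warning(sprintf("exclusion id(s) not found in records: %s",
                    paste(missing, collapse = ", ")))
  list(kept = records[!hit], removed = records[hit], missing = missing)
}
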
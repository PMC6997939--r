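#' Read a QIIME-style two-column taxonomy map
#'
#' Expects tab-separated lines `accession<TAB>Phylum;Class;Order;Family;
#' Genus;Species`.  Empty rank fields become the `"NA"` token.  Lines with
#' fewer than six ranks are right-padded with NA (a warning reports how
#' many); more than six ranks is a format error.
#'
#' @param path File path.
#' @param lenient If `TRUE`, duplicate accessions and over-long lineages
#'   are dropped with a warning instead of aborting.
#' @return A [TaxonomyMap-class].
#' @export
readTaxonomyMap <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(TaxonomyMap())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop(sprintf("expected 2 tab-separated columns, got %d on line %d",
                 lengths(parts)[which(lengths(parts) != 2L)[1]],
                 which(lengths(parts) != 2L)[1]))
  acc <- vapply(parts, `[`, character(1), 1L)
  lin <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  # strsplit drops a trailing empty field ("a;b;;" -> 3), so count the
  # separators directly to distinguish short lines from empty-rank lines
  nfield <- lengths(regmatches(vapply(parts, `[`, character(1), 2L),
                               gregexpr(";", vapply(parts, `[`,
                                                    character(1), 2L),
                                        fixed = TRUE))) + 1L
  over <- nfield > 6L
  if (any(over)) {
    msg <- sprintf("more than six ranks on line(s): %s",
                   paste(which(over), collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg)
    acc <- acc[!over]; lin <- lin[!over]; nfield <- nfield[!over]
  }
  short <- nfield < 6L
  if (any(short))
    warning(sprintf("%d line(s) had fewer than six ranks; padded with NA",
                    sum(short)))
  mat <- t(vapply(lin, function(v) {
    v <- v[seq_len(min(length(v), 6L))]
    c(v, rep(NA_TOKEN, 6L - length(v)))
  }, character(6)))
  dup <- duplicated(acc)
  if (any(dup)) {
    msg <- sprintf("duplicate accession(s): %s",
                   paste(unique(acc[dup]), collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg)
    acc <- acc[!dup]; mat <- mat[!dup, , drop = FALSE]
  }
  TaxonomyMap(acc, mat)
}

#' Write a TaxonomyMap in QIIME two-column format
#'
#' @param taxmap A [TaxonomyMap-class].
#' @param path Output path.
#' @param greengenesPrefixes If `TRUE`, prepend Greengenes-style rank
#'   prefixes (`p__`, `c__`, `o__`, `f__`, `g__`, `s__`) to each rank name
#'   for QIIME 2 import; NA ranks become the bare prefix.  Default
#'   `FALSE`: plain names, the format [readTaxonomyMap()] round-trips.
#' @return `path`, invisibly.
#' @export
writeTaxonomyMap <- function(taxmap, path, greengenesPrefixes = FALSE) {
  tab <- taxmap@table
  mat <- as.matrix(tab[RANKS])
  if (greengenesPrefixes) {
    pref <- c("p__", "c__", "o__", "f__", "g__", "s__")
    mat[mat == NA_TOKEN] <- ""
    for (j in seq_along(pref)) mat[, j] <- paste0(pref[j], mat[, j])
  }
  lineage <- apply(mat, 1, paste, collapse = ";")
  writeLines(if (nrow(tab)) paste(tab$accession, lineage, sep = "\t")
             else character(), path)
  invisible(path)
}

#' Subset a TaxonomyMap to a set of accessions
#'
#' @param taxmap A [TaxonomyMap-class].
#' @param accessions Character vector; every accession must be present.
#' @return A [TaxonomyMap-class] in the order given.
#' @export
subsetTaxonomyMap <- function(taxmap, accessions) {
  i <- match(accessions, taxmap@table$accession)
  if (anyNA(i))
    stop(sprintf("accession(s) not in taxonomy map: %s",
                 paste(accessions[is.na(i)], collapse = ", ")))
  tm <- taxmap@table[i, , drop = FALSE]
  TaxonomyMap(tm$accession, as.matrix(tm[RANKS]))
}
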
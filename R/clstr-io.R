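#' Parse a CD-HIT style .clstr file
#'
#' Understands the CD-HIT 4.x dialect: cluster headers `>Cluster N`,
#' member lines `idx<TAB><len>nt, >ACC... *` (representative) or
#' `idx<TAB><len>nt, >ACC... at +/99.17%` (member, strand and identity).
#' The accession is parsed up to the literal `...` terminator, so
#' accessions containing `...` are unsupported.
#'
#' @param path .clstr file path.
#' @param lenient If `TRUE`, clusters with zero members or with a missing
#'   or duplicated representative marker are dropped with a warning
#'   instead of aborting.
#' @return A [ClusterSet-class] in file order, with member identities
#'   filled from the percentages (1 for the representative).
#' @export
parseClstr <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, ">")
  if (length(lines) && !is_hdr[1])
    stop("malformed .clstr: does not start with a cluster header")
  grp <- cumsum(is_hdr)

  ids <- integer(); reps <- character()
  mem <- list(); idn <- list()
  bad <- function(msg) if (lenient) { warning(msg); FALSE } else stop(msg)

  for (g in seq_len(max(grp, 0))) {
    block <- lines[grp == g]
    hdr <- block[1]
    cid <- suppressWarnings(as.integer(sub("^>Cluster\\s+", "", hdr)))
    if (is.na(cid)) {
      if (!bad(sprintf("malformed cluster header: '%s'", hdr))) next
    }
    body <- block[-1]
    if (length(body) == 0L) {
      if (!bad(sprintf("cluster %d has zero members", cid))) next
    }
    m <- regmatches(body,
                    regexec("^\\d+\\t(\\d+)nt, >(.*?)\\.\\.\\. (.*)$", body))
    ok <- lengths(m) == 4L
    if (!all(ok)) {
      if (!bad(sprintf("cluster %d: unparseable member line '%s'",
                       cid, body[which(!ok)[1]]))) next
    }
    acc <- vapply(m, `[`, character(1), 3L)
    tail <- vapply(m, `[`, character(1), 4L)
    is_rep <- tail == "*"
    if (sum(is_rep) != 1L) {
      if (!bad(sprintf(
        "cluster %d: expected exactly one representative ('*') line, found %d",
        cid, sum(is_rep)))) next
    }
    pm <- regmatches(tail, regexec("^at [+-]/([0-9.]+)%$", tail))
    idfrac <- vapply(seq_along(tail), function(i) {
      if (is_rep[i]) return(1)
      if (length(pm[[i]]) == 2L) as.numeric(pm[[i]][2]) / 100 else NA_real_
    }, numeric(1))
    ids <- c(ids, cid)
    reps <- c(reps, acc[is_rep])
    mem <- c(mem, list(acc))
    idn <- c(idn, list(idfrac))
  }
  clusterSet(ids, reps, CharacterList(mem), NumericList(idn))
}

#' Write a ClusterSet as a CD-HIT style .clstr file
#'
#' Emits the exact dialect [parseClstr()] reads: the representative line
#' ends in `*`, other members in `at +/NN.NN%`.  Member lengths are looked
#' up in `records`.
#'
#' @param clusters A [ClusterSet-class].
#' @param records DNAStringSet covering every member accession.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClstr <- function(clusters, records, path) {
  widths <- setNames(width(records), names(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(clusters@ids)) {
    writeLines(sprintf(">Cluster %d", clusters@ids[i]), con)
    mem <- clusters@members[[i]]
    idn <- clusters@identities[[i]]
    rep_acc <- clusters@representatives[i]
    miss <- setdiff(mem, names(widths))
    if (length(miss))
      stop(sprintf("no sequence record for member(s): %s",
                   paste(miss, collapse = ", ")))
    for (j in seq_along(mem)) {
      tail <- if (mem[j] == rep_acc) "*" else
        sprintf("at +/%.2f%%", 100 * idn[j])
      writeLines(sprintf("%d\t%dnt, >%s... %s",
                         j - 1L, widths[[mem[j]]], mem[j], tail), con)
    }
  }
  invisible(path)
}
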
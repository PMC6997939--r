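# Independent oracles and small fixture builders.
#
# The alignment oracles are deliberately coded without reference to the
# package's aligner: one enumerates every global alignment recursively
# (exact for short sequences), the other is a straight-line matrix DP in
# plain R.  Both report (best score, max identical columns among
# score-optimal alignments).

# exhaustive recursion over all global alignments; exponential, use only
# for sequences of length <= ~6
enumerate_alignment <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$matches <- -Inf
  recurse <- function(i, j, score, matches) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score) {
        best$score <- score
        best$matches <- matches
      } else if (score == best$score && matches > best$matches) {
        best$matches <- matches
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      eq <- a[i] == b[j]
      recurse(i + 1, j + 1, score + if (eq) match else mismatch,
              matches + as.integer(eq))
    }
    if (i <= length(a)) recurse(i + 1, j, score + gap, matches)
    if (j <= length(b)) recurse(i, j + 1, score + gap, matches)
  }
  recurse(1L, 1L, 0, 0L)
  list(score = best$score, matches = best$matches)
}

# plain-R Needleman-Wunsch matrix DP, linear gaps; second matrix tracks
# max matches over score-optimal predecessors
nw_matrix_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  S[1, ] <- (0:m) * gap
  S[, 1] <- (0:n) * gap
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    eq <- av[i - 1] == bv[j - 1]
    cand <- c(S[i - 1, j - 1] + if (eq) match else mismatch,
              S[i - 1, j] + gap, S[i, j - 1] + gap)
    S[i, j] <- max(cand)
    mm <- -Inf
    if (cand[1] == S[i, j]) mm <- max(mm, M[i - 1, j - 1] + as.integer(eq))
    if (cand[2] == S[i, j]) mm <- max(mm, M[i - 1, j])
    if (cand[3] == S[i, j]) mm <- max(mm, M[i, j - 1])
    M[i, j] <- as.integer(mm)
  }
  list(score = S[n + 1, m + 1], matches = M[n + 1, m + 1])
}

oracle_identity <- function(a, b, ...) {
  nw_matrix_oracle(a, b, ...)$matches / min(nchar(a), nchar(b))
}

# straight-line restatement of the greedy clustering rule: order by
# length desc then accession asc; first-fit against representatives in
# creation order; uses the plain-R identity oracle throughout
reference_greedy_cluster <- function(seqs, accs, threshold) {
  ord <- order(-nchar(seqs), accs, method = "radix")
  seqs <- seqs[ord]; accs <- accs[ord]
  reps <- integer()
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assign_to[i] <- 0L
    for (k in seq_along(reps)) {
      if (oracle_identity(seqs[i], seqs[reps[k]]) >= threshold) {
        assign_to[i] <- k
        break
      }
    }
    if (assign_to[i] == 0L) {
      reps <- c(reps, i)
      assign_to[i] <- length(reps)
    }
  }
  lapply(seq_along(reps), function(k)
    list(representative = accs[reps[k]], members = accs[assign_to == k]))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# taxonomy map builder: one accession per element; genus/family defaults
# derived from species unless given
mk_tax <- function(accs, species,
                   genus = sub("^(\\S+).*$", "\\1", species),
                   family = rep("FamA", length(accs)),
                   order = rep("OrdA", length(accs)),
                   class = rep("ClsA", length(accs)),
                   phylum = rep("PhyA", length(accs))) {
  TaxonomyMap(accs, cbind(phylum, class, order, family, genus, species))
}

mk_cluster_set <- function(members, representative, id = 0L) {
  clusterSet(id, representative, IRanges::CharacterList(list(members)))
}
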
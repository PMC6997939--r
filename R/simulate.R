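#' Configuration for the synthetic fixture generator
#'
#' Describes a hierarchically structured taxon set and the sequence
#' divergence between its levels.  Defaults model the regime the 99%
#' clustering / 90% dominance rules assume for a barcode reference:
#' near-identical sequences within a species (0.2% substitutions per
#' site from the species consensus, hence ~99.6% expected pairwise
#' identity within species), clearly diverged species within a genus
#' (5% per site from the genus ancestor) and strongly diverged genera
#' (12% per site from the family ancestor).  Default sequence length is
#' 300 nt, comfortably above the 150 nt length filter so length
#' filtering is opt-in.  The default taxon counts (4 families x 5
#' genera x 3 species x 6 sequences = 360 records over 60 species) are
#' the package's standard benchmark fixture.
#'
#' @param nFamilies,generaPerFamily,speciesPerGenus,seqsPerSpecies
#'   Positive integers shaping the taxonomy.
#' @param seqLength Sequence length in nt.
#' @param intraSpeciesDivergence,interSpeciesDivergence,
#'   interGenusDivergence Per-site substitution probabilities applied at
#'   each hierarchy step; must be ordered intra < inter-species <
#'   inter-genus.
#' @param mislabelRate Fraction of records whose *emitted* taxonomy gets
#'   a wrong species label (truth retains reality).
#' @param keywordRate Fraction of records whose description gets one of
#'   the flagged header keywords injected.
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @return A named list of class `fixtureConfig`.
#' @export
fixtureConfig <- function(nFamilies = 4L, generaPerFamily = 5L,
                          speciesPerGenus = 3L, seqsPerSpecies = 6L,
                          seqLength = 300L,
                          intraSpeciesDivergence = 0.002,
                          interSpeciesDivergence = 0.05,
                          interGenusDivergence = 0.12,
                          mislabelRate = 0, keywordRate = 0,
                          seed = 1L) {
  cfg <- list(nFamilies = as.integer(nFamilies),
              generaPerFamily = as.integer(generaPerFamily),
              speciesPerGenus = as.integer(speciesPerGenus),
              seqsPerSpecies = as.integer(seqsPerSpecies),
              seqLength = as.integer(seqLength),
              intraSpeciesDivergence = intraSpeciesDivergence,
              interSpeciesDivergence = interSpeciesDivergence,
              interGenusDivergence = interGenusDivergence,
              mislabelRate = mislabelRate, keywordRate = keywordRate,
              seed = as.integer(seed))
  with(cfg, {
    if (nFamilies < 1L || generaPerFamily < 1L || speciesPerGenus < 1L ||
        seqsPerSpecies < 1L)
      stop("taxon and sequence counts must all be >= 1")
    if (seqLength < 1L) stop("seqLength must be >= 1")
    if (!(intraSpeciesDivergence < interSpeciesDivergence &&
          interSpeciesDivergence < interGenusDivergence))
      stop("divergences must be ordered intra < inter-species < inter-genus")
    if (any(c(mislabelRate, keywordRate) < 0) ||
        any(c(mislabelRate, keywordRate) > 1))
      stop("rates must lie in [0, 1]")
  })
  structure(cfg, class = "fixtureConfig")
}

#' Generate the systematic taxonomy skeleton
#'
#' Systematic, collision-free names (`Fam01`, `Gen01_01`, `Sp01_01_01`)
#' under one fixed synthetic phylum/class/order, so that fixture log
#' files are human-diffable.  Deterministic for a given config.
#'
#' @param config A [fixtureConfig()].
#' @return `list(species=, lineages=)`: the species name vector and a
#'   character matrix (one row per species, six rank columns).
#' @export
generateTaxonomy <- function(config) {
  stopifnot(inherits(config, "fixtureConfig"))
  fam <- sprintf("Fam%02d", seq_len(config$nFamilies))
  rows <- list()
  for (f in seq_len(config$nFamilies))
    for (g in seq_len(config$generaPerFamily))
      for (s in seq_len(config$speciesPerGenus)) {
        rows[[length(rows) + 1L]] <- c(
          phylum = "Phylum01", class = "Class01", order = "Order01",
          family = fam[f],
          genus = sprintf("Gen%02d_%02d", f, g),
          species = sprintf("Sp%02d_%02d_%02d", f, g, s))
      }
  lineages <- do.call(rbind, rows)
  list(species = unname(lineages[, "species"]), lineages = lineages)
}

# mutate a sequence: substitute each site with probability p, drawing a
# different base uniformly
.mutateSeq <- function(chars, p) {
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(alt, b), 1L), character(1))
  }
  chars
}

#' Generate a taxonomy-structured synthetic sequence set
#'
#' Evolves sequences down the taxonomy: one random ancestor per family,
#' genus ancestors mutated from it at the inter-genus rate, species
#' consensus sequences mutated from the genus ancestor at the
#' inter-species rate, and individual records mutated from the species
#' consensus at the intra-species rate (substitutions only, so identity
#' arithmetic stays analyzable).  A `mislabelRate` fraction of records is
#' given a different species' full lineage in the *emitted* taxonomy
#' while `truth` keeps the real one; a `keywordRate` fraction gets one
#' of the flagged header keywords injected into its description.
#'
#' @param config A [fixtureConfig()].
#' @return `list(records=, taxonomy=, truth=, planted=)`: the records
#'   (DNAStringSet), the emitted [TaxonomyMap-class], the true
#'   TaxonomyMap, and a data.frame of planted perturbations with columns
#'   `accession`, `kind` (`"mislabel"` or `"keyword"`), `detail`.
#' @export
generateSequences <- function(config) {
  stopifnot(inherits(config, "fixtureConfig"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  taxo <- generateTaxonomy(config)
  nsp <- length(taxo$species)
  bases <- c("A", "C", "G", "T")

  acc <- character(); seqs <- character(); sp_of <- integer()
  for (f in seq_len(config$nFamilies)) {
    fam_anc <- sample(bases, config$seqLength, replace = TRUE)
    for (g in seq_len(config$generaPerFamily)) {
      gen_anc <- .mutateSeq(fam_anc, config$interGenusDivergence)
      for (s in seq_len(config$speciesPerGenus)) {
        sp_cons <- .mutateSeq(gen_anc, config$interSpeciesDivergence)
        sp_idx <- (f - 1L) * config$generaPerFamily *
          config$speciesPerGenus + (g - 1L) * config$speciesPerGenus + s
        for (r in seq_len(config$seqsPerSpecies)) {
          acc <- c(acc, sprintf("S%02d%02d%02d%02d", f, g, s, r))
          seqs <- c(seqs,
                    paste(.mutateSeq(sp_cons,
                                     config$intraSpeciesDivergence),
                          collapse = ""))
          sp_of <- c(sp_of, sp_idx)
        }
      }
    }
  }
  n <- length(acc)
  desc <- paste(taxo$species[sp_of], "ribosomal spacer region, synthetic")

  truth_lin <- taxo$lineages[sp_of, , drop = FALSE]
  emit_lin <- truth_lin
  planted <- data.frame(accession = character(), kind = character(),
                        detail = character(), stringsAsFactors = FALSE)

  n_mis <- round(config$mislabelRate * n)
  if (n_mis > 0L && nsp > 1L) {
    mis <- sample(n, n_mis)
    for (i in mis) {
      wrong <- sample(setdiff(seq_len(nsp), sp_of[i]), 1L)
      emit_lin[i, ] <- taxo$lineages[wrong, ]
      planted <- rbind(planted, data.frame(
        accession = acc[i], kind = "mislabel",
        detail = taxo$species[wrong], stringsAsFactors = FALSE))
    }
  }
  n_kw <- round(config$keywordRate * n)
  if (n_kw > 0L) {
    kwi <- sample(n, n_kw)
    for (i in kwi) {
      kw <- sample(DEFAULT_KEYWORDS, 1L)
      desc[i] <- paste0(toupper(kw), ": ", desc[i])
      planted <- rbind(planted, data.frame(
        accession = acc[i], kind = "keyword", detail = kw,
        stringsAsFactors = FALSE))
    }
  }

  list(records = seqRecords(seqs, acc, desc),
       taxonomy = TaxonomyMap(acc, emit_lin),
       truth = TaxonomyMap(acc, truth_lin),
       planted = planted)
}
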
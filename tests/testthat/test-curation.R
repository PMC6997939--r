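# convenience: records of equal length for cluster members
mk_recs <- function(accs, len = 200) {
  seqRecords(vapply(seq_along(accs),
                    function(i) strrep("ACGT", len / 4), character(1)),
             accs)
}

test_that("composition tallies count informative members only, once each", {
  accs <- sprintf("A%02d", 1:10)
  tm <- mk_tax(accs, rep("Quercus robur", 10))
  t1 <- tallyComposition(accs, tm, "species")
  expect_equal(t1$counts, c("Quercus robur" = 10L))
  expect_equal(t1$nInformative, 10L)
  expect_equal(t1$nNA, 0L)

  tm2 <- mk_tax(accs, c(rep("Quercus robur", 9), "NA"))
  t2 <- tallyComposition(accs, tm2, "species")
  expect_equal(t2$counts, c("Quercus robur" = 9L))
  expect_equal(t2$nInformative, 9L)
  expect_equal(t2$nNA, 1L)

  tm3 <- mk_tax(accs[1:3], c("X", "Y", "Z"))
  t3 <- tallyComposition(accs[1:3], tm3, "species")
  expect_equal(t3$counts, c(X = 1L, Y = 1L, Z = 1L))

  expect_error(tallyComposition(c(accs[1], "MISSING"), tm, "species"),
               "MISSING")
})

test_that("a homogeneous cluster resolves at species level", {
  accs <- sprintf("A%02d", 1:10)
  tm <- mk_tax(accs, rep("Quercus robur", 10), genus = rep("Quercus", 10))
  dec <- evaluateCluster(0L, accs, accs[1], tm, mk_recs(accs))
  expect_equal(dec@resolvedRank, "species")
  expect_equal(dec@dominantTaxon, "Quercus robur")
  expect_equal(dec@representative, accs[1])
  expect_length(dec@flags, 0)
})

test_that("exactly 90% escalates (strict rule) while >90% resolves", {
  cases <- list(
    list(n_dom = 9L, n_min = 1L, rank = "genus"),     # 0.9 fails
    list(n_dom = 18L, n_min = 2L, rank = "genus"),    # 0.9 fails
    list(n_dom = 10L, n_min = 1L, rank = "species"),  # 10/11 resolves
    list(n_dom = 19L, n_min = 2L, rank = "species"))  # 19/21 resolves
  for (cs in cases) {
    n <- cs$n_dom + cs$n_min
    accs <- sprintf("A%02d", seq_len(n))
    tm <- mk_tax(accs,
                 c(rep("Quercus robur", cs$n_dom),
                   rep("Quercus petraea", cs$n_min)),
                 genus = rep("Quercus", n))
    dec <- evaluateCluster(0L, accs, accs[1], tm, mk_recs(accs))
    expect_equal(dec@resolvedRank, cs$rank,
                 info = sprintf("%d/%d", cs$n_dom, n))
    if (cs$rank == "genus") {
      expect_equal(dec@dominantTaxon, "Quercus")
      expect_equal(dec@tallies$genus, c(Quercus = n))
    } else {
      expect_equal(dec@dominantTaxon, "Quercus robur")
    }
    expect_true("multi_species" %in% dec@flags)
  }
})

test_that("the escalation ladder walks species, genus, family, discarded", {
  # genus-resolved: two species of one genus, 50/50
  accs <- sprintf("B%02d", 1:10)
  tm <- mk_tax(accs, rep(c("Quercus robur", "Quercus petraea"), 5),
               genus = rep("Quercus", 10))
  dec <- evaluateCluster(1L, accs, accs[1], tm, mk_recs(accs))
  expect_equal(dec@resolvedRank, "genus")

  # family-resolved: three genera of one family
  tm2 <- mk_tax(accs, sprintf("Sp%d", rep(1:3, length.out = 10)),
                genus = sprintf("Gen%d", rep(1:3, length.out = 10)),
                family = rep("Fagaceae", 10))
  dec2 <- evaluateCluster(2L, accs, accs[1], tm2, mk_recs(accs))
  expect_equal(dec2@resolvedRank, "family")
  expect_equal(dec2@dominantTaxon, "Fagaceae")

  # discarded: three families, none above 90%
  accs3 <- sprintf("C%d", 1:3)
  tm3 <- mk_tax(accs3, sprintf("Sp%d", 1:3), genus = sprintf("Gen%d", 1:3),
                family = sprintf("Fam%d", 1:3))
  dec3 <- evaluateCluster(3L, accs3, accs3[1], tm3, mk_recs(accs3))
  expect_equal(dec3@resolvedRank, "discarded")
  expect_true(is.na(dec3@dominantTaxon))
  expect_true(is.na(dec3@representative))
})

test_that("members NA at a rank leave numerator and denominator; empty ranks escalate", {
  accs <- sprintf("D%02d", 1:10)
  # 9 informative members of one species + 1 NA: 9/9 > 0.9 resolves
  tm <- mk_tax(accs, c(rep("Quercus robur", 9), "NA"),
               genus = rep("Quercus", 10))
  dec <- evaluateCluster(0L, accs, accs[1], tm, mk_recs(accs))
  expect_equal(dec@resolvedRank, "species")

  # all species NA: species rank uninformative, genus resolves
  tm2 <- mk_tax(accs, rep("NA", 10), genus = rep("Quercus", 10))
  dec2 <- evaluateCluster(0L, accs, accs[1], tm2, mk_recs(accs))
  expect_equal(dec2@resolvedRank, "genus")
  expect_false("multi_species" %in% dec2@flags)
})

test_that("more than two species raises the highlight flag", {
  accs <- sprintf("E%02d", 1:30)
  tm <- mk_tax(accs, c(rep("SpA", 28), "SpB", "SpC"),
               genus = rep("GenA", 30))
  dec <- evaluateCluster(0L, accs, accs[1], tm, mk_recs(accs))
  expect_equal(dec@resolvedRank, "species")   # 28/30 > 0.9
  expect_true(all(c("multi_species", "gt2_species") %in% dec@flags))

  tm2 <- mk_tax(accs, c(rep("SpA", 29), "SpB"), genus = rep("GenA", 30))
  dec2 <- evaluateCluster(0L, accs, accs[1], tm2, mk_recs(accs))
  expect_false("gt2_species" %in% dec2@flags)
})

test_that("minority representatives are replaced by the longest dominant member", {
  accs <- sprintf("F%02d", 1:21)
  species <- c(rep("Quercus robur", 19), rep("Fagus sylvatica", 2))
  tm <- mk_tax(accs, species,
               genus = c(rep("Quercus", 19), rep("Fagus", 2)))
  # the incoming representative F21 is a minority member and the longest
  lens <- c(seq(200, 236, length.out = 19), 300, 400)
  recs <- seqRecords(vapply(round(lens / 4) * 4,
                            function(l) strrep("ACGT", l / 4),
                            character(1)), accs)
  dec <- evaluateCluster(0L, accs, "F21", tm, recs)
  expect_equal(dec@resolvedRank, "species")   # 19/21 > 0.9
  expect_true("rep_replaced" %in% dec@flags)
  # longest Quercus robur member is F19
  expect_equal(dec@representative, "F19")

  # tie on length breaks by accession, ascending
  recs2 <- mk_recs(accs)
  dec2 <- evaluateCluster(0L, accs, "F21", tm, recs2)
  expect_equal(dec2@representative, "F01")

  # a representative already in the dominant taxon is kept
  dec3 <- evaluateCluster(0L, accs, "F05", tm, recs)
  expect_equal(dec3@representative, "F05")
  expect_false("rep_replaced" %in% dec3@flags)
})

test_that("output lineages blank exactly the ranks finer than the resolution", {
  accs <- sprintf("G%02d", 1:10)
  tm <- mk_tax(accs, rep(c("Quercus robur", "Quercus petraea"), 5),
               genus = rep("Quercus", 10), family = rep("Fagaceae", 10))
  dec <- evaluateCluster(0L, accs, accs[1], tm, mk_recs(accs))
  expect_equal(dec@resolvedRank, "genus")
  ot <- buildOutputTaxonomy(dec, accs, tm)
  expect_equal(unname(ot$lineage),
               c("PhyA", "ClsA", "OrdA", "Fagaceae", "Quercus", "NA"))
  expect_false(ot$conflict)

  # species-resolved lineage passes through unchanged
  tm2 <- mk_tax(accs, rep("Quercus robur", 10), genus = rep("Quercus", 10))
  dec2 <- evaluateCluster(0L, accs, accs[1], tm2, mk_recs(accs))
  ot2 <- buildOutputTaxonomy(dec2, accs, tm2)
  expect_equal(unname(ot2$lineage[6]), "Quercus robur")

  # family-resolved blanks genus and species
  tm3 <- mk_tax(accs, sprintf("Sp%d", rep(1:3, length.out = 10)),
                genus = sprintf("Gen%d", rep(1:3, length.out = 10)),
                family = rep("Fagaceae", 10))
  dec3 <- evaluateCluster(0L, accs, accs[1], tm3, mk_recs(accs))
  ot3 <- buildOutputTaxonomy(dec3, accs, tm3)
  expect_equal(unname(ot3$lineage[5:6]), c("NA", "NA"))

  # a coarser-rank disagreement is flagged but the representative wins
  tm4 <- mk_tax(accs, rep("Quercus robur", 10), genus = rep("Quercus", 10),
                family = c(rep("Fagaceae", 9), "Betulaceae"))
  dec4 <- evaluateCluster(0L, accs, accs[1], tm4, mk_recs(accs))
  ot4 <- buildOutputTaxonomy(dec4, accs, tm4)
  expect_true(ot4$conflict)
  expect_equal(unname(ot4$lineage["family"]), "Fagaceae")
})

test_that("whole-round curation composes decisions, outputs and detail", {
  # five clean clusters + one 9/1 two-genus... + one 3-family discard
  accs <- c(sprintf("H%02d", 1:25),   # 5 clusters x 5, clean
            sprintf("I%02d", 1:10),   # 9+1 two species, genus-resolved
            sprintf("J%d", 1:3))      # 3 families, discarded
  species <- c(rep(sprintf("Sp%d", 1:5), each = 5),
               c(rep("SpX", 9), "SpY"),
               sprintf("SpJ%d", 1:3))
  genus <- c(rep(sprintf("Gen%d", 1:5), each = 5),
             rep("GenX", 10),
             sprintf("GenJ%d", 1:3))
  family <- c(rep("FamA", 35), sprintf("FamJ%d", 1:3))
  tm <- mk_tax(accs, species, genus = genus, family = family)
  recs <- mk_recs(accs)
  cl <- clusterSet(0:6,
                   c(sprintf("H%02d", seq(1, 25, by = 5)), "I01", "J1"),
                   IRanges::CharacterList(split(accs,
                                                rep(1:7, c(5, 5, 5, 5, 5,
                                                           10, 3)))))
  cur <- runCuration(cl, tm, recs)
  d <- decisions(cur$report)
  expect_equal(nrow(d), 7L)
  expect_equal(sum(d$resolved_rank == "species"), 5L)
  expect_equal(sum(d$resolved_rank == "genus"), 1L)
  expect_equal(sum(d$resolved_rank == "discarded"), 1L)
  cnt <- curationCounts(cur$report)
  # the 9+1 cluster and the discarded 3-species cluster are both
  # multi-species; only the discarded one exceeds the >2-species highlight
  expect_equal(unname(cnt["multi_species"]), 2L)
  expect_equal(unname(cnt["gt2_species"]), 1L)
  expect_equal(unname(cnt["discarded"]), 1L)

  # one output record and taxonomy line per kept cluster
  expect_equal(length(cur$records), 6L)
  expect_equal(length(cur$taxonomy), 6L)
  expect_setequal(names(cur$records), accessions(cur$taxonomy))
  # the genus-resolved cluster emits species NA
  gen_rep <- d$representative[d$resolved_rank == "genus"]
  expect_equal(unname(lineageOf(cur$taxonomy, gen_rep)["species"]), "NA")
  # discarded cluster appears in detail with all member lineages
  expect_equal(names(cur$report@discardedDetail), "6")
  expect_equal(cur$report@discardedDetail[["6"]]$accession,
               sprintf("J%d", 1:3))
})

test_that("curation is deterministic and its dominance is independently sound", {
  fx <- generateSequences(fixtureConfig(nFamilies = 2L,
                                        generaPerFamily = 3L,
                                        speciesPerGenus = 2L,
                                        seqsPerSpecies = 5L,
                                        seqLength = 200L,
                                        mislabelRate = 0.05, seed = 9L))
  cl <- greedyCluster(fx$records, 0.99)
  cur1 <- runCuration(cl, fx$taxonomy, fx$records)
  cur2 <- runCuration(cl, fx$taxonomy, fx$records)
  expect_identical(decisions(cur1$report), decisions(cur2$report))
  expect_identical(as.character(cur1$records), as.character(cur2$records))

  d <- decisions(cur1$report)
  for (k in seq_len(nrow(d))) {
    if (d$resolved_rank[k] == "discarded") next
    mem <- clusterMembers(cl)[[k]]
    t <- tallyComposition(mem, fx$taxonomy, d$resolved_rank[k])
    expect_gt(t$counts[[d$dominant_taxon[k]]] / t$nInformative, 0.9)
    expect_true(d$representative[k] %in% mem)
    # representative carries the dominant taxon at the resolved rank
    expect_equal(unname(lineageOf(fx$taxonomy,
                                  d$representative[k])[d$resolved_rank[k]]),
                 d$dominant_taxon[k])
  }
})
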
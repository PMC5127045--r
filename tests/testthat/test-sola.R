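test_that("every heavy atom of amitriptyline yields one type-1 SoLA", {
  ami <- parseFixture("amitriptyline")
  nAtom <- which(atoms(ami)$element == "N" & !atoms(ami)$hydrogen)
  s1 <- buildSolas(ami, nAtom, "N_dealkylation", "type1")
  expect_equal(nrow(s1), 21)
  expect_equal(sum(s1$positive), 1)
  expect_equal(sum(!s1$positive), 20)
  # type 2 restricts to the class element: amitriptyline has a single N
  s2 <- buildSolas(ami, nAtom, "N_dealkylation", "type2")
  expect_equal(nrow(s2), 1)
  expect_equal(sum(s2$positive), 1)
})

test_that("SoLA generation handles empty positives and element mismatches", {
  tol <- parseFixture("toluene")
  s <- buildSolas(tol, integer(0), "aliphatic_hydroxylation", "type1")
  expect_equal(nrow(s), heavyAtomCount(tol))
  expect_false(any(s$positive))
  expect_error(buildSolas(tol, 1L, "N_dealkylation", "type1"),
               "data-consistency")
  expect_error(buildSolas(tol, 99L, "aliphatic_hydroxylation", "type1"),
               "heavy atoms")
})

test_that("training-set assembly pools per class with union positives", {
  tol <- parseFixture("toluene")
  # two hydroxylations of the same substrate at inequivalent sites
  recA <- ReactionRecord(tol, parseMolecule("Cc1ccccc1O", name = "o-cresol"),
                         "CYP2E1", "aromatic_hydroxylation")
  recB <- ReactionRecord(tol, parseMolecule("Cc1ccc(O)cc1", name = "p-cresol"),
                         "CYP2E1", "aromatic_hydroxylation")
  ani <- parseFixture("anisole")
  recC <- applyRule(ani, transformationRules()$O_dealkylation, seed = 1)

  ts <- assembleTrainingSet(list(recA, recB, recC), "aromatic_hydroxylation",
                            "type1")
  expect_length(trainingMolecules(ts), 2)
  s <- solas(ts)
  # ortho record labels the symmetry-equivalent pair {3,7}, para adds {5}
  expect_setequal(s$atom[s$mol == 1 & s$positive], c(3L, 5L, 7L))
  expect_false(any(s$positive[s$mol == 2]))        # anisole: negatives only
  expect_equal(nrow(s), heavyAtomCount(tol) + heavyAtomCount(ani))

  # the merged hydroxylation class unions its members: the ortho pair plus
  # the three equivalent methyls of the aliphatic record
  recD <- applyRule(parseMolecule("CC(C)(C)CCO", name = "neo"),
                    transformationRules()$aliphatic_hydroxylation, seed = 1)
  tsH <- assembleTrainingSet(list(recA, recD), "hydroxylation", "type1")
  expect_equal(sum(solas(tsH)$positive), 5)

  expect_error(assembleTrainingSet(list(recC), "S_oxidation", "type1"),
               "untrainable")
})

test_that("type-2 sets are subsets of type-1 sets with identical positives", {
  bm <- smallBenchmark()
  records <- lapply(bm$records[1:40], mapReactionRecord)
  for (cls in c("O_dealkylation", "N_oxidation")) {
    t1 <- tryCatch(assembleTrainingSet(records, cls, "type1"),
                   error = function(e) NULL)
    t2 <- tryCatch(assembleTrainingSet(records, cls, "type2"),
                   error = function(e) NULL)
    if (is.null(t1) || is.null(t2)) next
    expect_lte(nrow(solas(t2)), nrow(solas(t1)))
    expect_equal(sum(solas(t2)$positive), sum(solas(t1)$positive))
    # type-1 SoLA count per molecule equals the heavy-atom count
    cnt <- table(solas(t1)$mol)
    expect_equal(as.integer(cnt),
                 vapply(trainingMolecules(t1), heavyAtomCount, 0L))
  }
})

test_that("assembly is order-independent over the record sequence", {
  bm <- smallBenchmark()
  records <- lapply(bm$records[1:25], mapReactionRecord)
  a <- assembleTrainingSet(records, "all_reactions", "type1")
  b <- assembleTrainingSet(rev(records), "all_reactions", "type1")
  sa <- solas(a); sb <- solas(b)
  keyA <- paste(vapply(trainingMolecules(a)[sa$mol], molName, ""), sa$atom)
  keyB <- paste(vapply(trainingMolecules(b)[sb$mol], molName, ""), sb$atom)
  expect_setequal(keyA[sa$positive], keyB[sb$positive])
  expect_setequal(keyA, keyB)
})
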
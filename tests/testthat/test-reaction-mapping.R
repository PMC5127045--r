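test_that("embeddings are exhaustive, element-preserving and deduplicated", {
  meoh <- parseMolecule("CO", name = "methanol")
  etoh <- parseMolecule("CCO", name = "ethanol")
  e <- findEmbeddings(meoh, etoh)
  expect_length(e, 1)
  # C maps onto the carbinol carbon, O onto O
  expect_equal(unname(e[[1]]), c(2L, 3L))

  ben <- parseFixture("benzene")
  tol <- parseFixture("toluene")
  expect_length(findEmbeddings(ben, tol), 12)  # 6 rotations x 2 reflections

  expect_gte(length(findEmbeddings(tol, tol)), 1)
  expect_error(findEmbeddings(tol, ben), "swap")
})

test_that("reacting atoms are identified for the worked examples", {
  tol <- parseFixture("toluene")
  bnz <- parseMolecule("OCc1ccccc1", name = "benzyl alcohol")
  m <- identifyReactingAtoms(tol, bnz)
  expect_equal(mappingDirection(m), "addition")
  expect_equal(reactingAtoms(m), 1L)                    # the methyl carbon
  expect_false(atoms(tol)$aromatic[reactingAtoms(m)])
  expect_equal(atoms(bnz)$element[changedFragment(m)], "O")

  clo <- parseFixture("clomiphene")
  des <- parseMolecule("CCNCCOc1ccc(cc1)C(=C(c2ccccc2)Cl)c3ccccc3",
                       name = "N-desethylclomiphene")
  m2 <- identifyReactingAtoms(clo, des)
  expect_equal(mappingDirection(m2), "removal")
  expect_equal(atoms(clo)$element[reactingAtoms(m2)], "N")
  expect_equal(assignReactionClass(m2, clo, des, "CYP2D6"), "N_dealkylation")

  expect_error(identifyReactingAtoms(tol, parseFixture("toluene")),
               "no structural change")
})

test_that("the class rule table assigns all nine elementary classes", {
  rules <- transformationRules()
  mols <- generateMolecules(25, seed = 5)
  seen <- character(0)
  for (m in mols) for (r in rules) {
    if (length(r$match(m)) == 0) next
    rec <- applyRule(m, r, seed = 1)
    mp <- identifyReactingAtoms(rec@substrate, rec@product,
                                classHint = r$reactionClass)
    expect_equal(assignReactionClass(mp, rec@substrate, rec@product,
                                     rec@enzyme),
                 r$reactionClass, label = paste(molName(m), r$name))
    seen <- union(seen, r$reactionClass)
  }
  expect_setequal(seen, reactionClasses())
})

test_that("glucuronidation is recognized from the fragment structure alone", {
  ph <- parseFixture("phenol")
  rec <- applyRule(ph, transformationRules()$O_glucuronidation, seed = 1)
  m <- identifyReactingAtoms(rec@substrate, rec@product)
  expect_length(changedFragment(m), 12)
  expect_equal(assignReactionClass(m, rec@substrate, rec@product, "UGT1A9"),
               "O_glucuronidation")
})

test_that("equal heavy-atom counts route through hydrogen-count changes", {
  etoh <- parseMolecule("CCO", name = "ethanol")
  ald <- parseMolecule("CC=O", name = "acetaldehyde")
  m <- identifyReactingAtoms(etoh, ald, classHint = "C_oxidation")
  expect_equal(mappingDirection(m), "none")
  expect_equal(reactingAtoms(m), 2L)  # the carbinol carbon
  expect_equal(assignReactionClass(m, etoh, ald, "CYP2C9"), "C_oxidation")
})

test_that("enzyme/class contradictions are flagged, not fatal", {
  tol <- parseFixture("toluene")
  bnz <- parseMolecule("OCc1ccccc1")
  m <- identifyReactingAtoms(tol, bnz)
  expect_warning(cls <- assignReactionClass(m, tol, bnz, "UGT"),
                 "contradicts")
  expect_equal(as.character(cls), "aliphatic_hydroxylation")
  expect_true(attr(cls, "inconsistent"))
})

test_that("reacting-atom sets are invariant under substrate atom reordering", {
  bm <- smallBenchmark()
  for (i in c(1, 7, 19, 30)) {
    rec <- bm$records[[i]]
    m0 <- identifyReactingAtoms(rec@substrate, rec@product)
    p <- permuteGraph(rec@substrate, seed = i)
    m1 <- identifyReactingAtoms(p$graph, rec@product)
    expect_setequal(p$map[reactingAtoms(m0)], reactingAtoms(m1))
  }
})

test_that("reaction tables read robustly and mapping reports round out", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("substrate_smiles\tproduct_smiles\tenzyme\tclass",
               "Cc1ccccc1\tOCc1ccccc1\tCYP3A4\taliphatic_hydroxylation",
               "C1CC\tCCO\tCYP3A4\t",
               "COc1ccccc1\tOc1ccccc1\tCYP2D6\tO_dealkylation"), path)
  tab <- readReactionTable(path)
  expect_length(tab$records, 2)
  expect_equal(tab$failures$row, 2)
  mapped <- lapply(tab$records, mapReactionRecord)
  rep <- writeMappingReport(mapped)
  expect_equal(rep$class, c("aliphatic_hydroxylation", "O_dealkylation"))
  expect_true(all(rep$consistent))
})
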
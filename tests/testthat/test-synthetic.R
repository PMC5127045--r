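test_that("molecule generation is seeded, bounded and parameter-respecting", {
  a <- generateMolecules(10, seed = 7)
  b <- generateMolecules(10, seed = 7)
  expect_identical(writeSDF(a), writeSDF(b))
  hv <- vapply(a, heavyAtomCount, 0L)
  expect_true(all(hv >= 6 & hv <= 30))
  # connectivity: single component
  for (g in a)
    expect_equal(igraph::components(
      metaboRA:::.heavySkeleton(g))$no, 1, label = molName(g))

  noHet <- generateMolecules(5, seed = 3, params = list(heteroatoms = FALSE))
  for (g in noHet)
    expect_true(all(atoms(g)$element %in% c("C", "H")))
  expect_error(generateMolecules(3, 1, params = list(substituents = "xx")),
               "unsatisfiable|subscript")
})

test_that("rules edit a matched site and record it as ground truth", {
  rules <- transformationRules()
  tol <- parseFixture("toluene")
  rec <- applyRule(tol, rules$aromatic_hydroxylation, seed = 4)
  expect_true(rec@trueAtom %in% c(3L, 7L))        # ortho pair
  expect_equal(heavyAtomCount(rec@product), heavyAtomCount(tol) + 1L)
  expect_error(applyRule(tol, rules$S_oxidation), "not applicable")
  expect_error(applyRule(tol, rules$aromatic_hydroxylation, site = 5L),
               "does not match")

  ani <- parseFixture("anisole")
  rec2 <- applyRule(ani, rules$O_dealkylation, seed = 1)
  expect_equal(rec2@trueAtom, 2L)                  # the ether oxygen
  expect_equal(canonicalSmiles(rec2@product), canonicalSmiles(parseFixture("phenol")))
})

test_that("the benchmark covers all nine classes and serializes deterministically", {
  bm <- smallBenchmark()
  expect_s3_class(bm, "SyntheticBenchmark")
  expect_setequal(unique(vapply(bm$records, slot, "", "declaredClass")),
                  reactionClasses())
  df1 <- writeReactionTable(bm)
  df2 <- writeReactionTable(makeBenchmark(nMolecules = 30L, seed = 11L))
  expect_identical(df1, df2)
  expect_named(df1, c("name", "substrate_smiles", "product_smiles",
                      "enzyme", "class", "true_atom"))
  # glucuronidation rows carry the UGT tag, others a CYP isoform
  gluc <- grepl("glucuronidation", df1$class)
  expect_true(all(df1$enzyme[gluc] == "UGT"))
  expect_true(all(df1$enzyme[!gluc] %in%
                  c("CYP1A2", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A4")))
})

test_that("benchmark records pass the mapping round-trip", {
  bm <- smallBenchmark()
  for (r in bm$records) {
    m <- identifyReactingAtoms(r@substrate, r@product,
                               classHint = r@declaredClass)
    expect_true(r@trueAtom %in% reactingAtoms(m),
                label = paste(molName(r@substrate), r@declaredClass))
  }
})

test_that("generated structures survive the SDF round-trip", {
  for (g in generateMolecules(8, seed = 31)) {
    blk <- strsplit(writeSDF(g), "\\$\\$\\$\\$")[[1]][1]
    expect_true(metaboRA:::.graphsIsomorphic(g, parseMolecule(blk, "molfile")),
                label = molName(g))
  }
})
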
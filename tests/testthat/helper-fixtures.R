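# shared fixtures: parsed literature compounds, atom-permutation helper,
# toy training-set builder and a memoized full-size benchmark

fx <- fixtureSmiles()

parseFixture <- function(name) parseMolecule(fx[[name]], name = name)

# permute the atom order of a graph; returns list(graph, map) with
# map[old] = new index
permuteGraph <- function(g, seed) {
  n <- nrow(atoms(g))
  perm <- withr::with_seed(seed, sample(n))   # perm[new] = old
  map <- order(perm)                          # map[old] = new
  a <- atoms(g)[perm, , drop = FALSE]
  b <- bonds(g)
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  list(graph = metaboRA:::.newMolecularGraph(a, b, name = molName(g)),
       map = map)
}

# training set over small random molecules with seeded random positives;
# guarantees >= 2 positives and >= 2 negatives
toyTrainingSet <- function(seed, nMol = 3, class = "all_reactions") {
  mols <- generateMolecules(nMol, seed = seed,
                            params = list(chainRange = c(4L, 4L),
                                          nSubstituents = c(2L, 2L)))
  solas <- do.call(rbind, lapply(seq_along(mols), function(k) {
    hv <- heavyAtoms(mols[[k]])
    data.frame(mol = k, atom = hv,
               element = atoms(mols[[k]])$element[hv],
               positive = FALSE, negative_type = "type1")
  }))
  npos <- withr::with_seed(seed, sample(2:4, 1))
  pos <- withr::with_seed(seed + 1, sample(nrow(solas), npos))
  solas$positive[pos] <- TRUE
  new("TrainingSet", reactionClass = class, negativeType = "type1",
      molecules = mols, solas = solas, provenance = "toy")
}

# full-size synthetic benchmark, built once per test run
.bmCache <- new.env(parent = emptyenv())
fullBenchmark <- function() {
  if (is.null(.bmCache$bm))
    .bmCache$bm <- makeBenchmark(nMolecules = 200L, seed = 42L)
  .bmCache$bm
}
smallBenchmark <- function() {
  if (is.null(.bmCache$small))
    .bmCache$small <- makeBenchmark(nMolecules = 30L, seed = 11L)
  .bmCache$small
}
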
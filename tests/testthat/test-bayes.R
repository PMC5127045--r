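# hand-buildable model for closed-form checks
mkModel <- function(N, Nk, d, Ni, Nik, posB = numeric(0), negB = numeric(0))
  new("ClassModel", reactionClass = "all_reactions", negativeType = "type1",
      maxLevel = 2L, levelsMode = "upto", grammar = "lmna/1",
      N = as.integer(N), Nk = as.integer(Nk), descriptors = d,
      Ni = as.integer(Ni), Nik = as.integer(Nik), posB = posB, negB = negB)

test_that("count tables give the raw frequency probabilities", {
  ts <- toyTrainingSet(2)
  model <- trainClassModel(ts)
  s <- solas(ts)
  expect_equal(model@N, nrow(s))
  expect_equal(model@Nk, sum(s$positive))
  expect_equal(priorProbability(model), sum(s$positive) / nrow(s))
  p <- conditionalProbabilities(model)
  expect_true(all(p >= 0 & p <= 1))
  # spot-check one descriptor against direct set membership
  sets <- metaboRA:::.trainingDescriptorSets(ts)
  d <- model@descriptors[which.max(model@Ni)]
  inSola <- vapply(sets, function(x) d %in% x, logical(1))
  expect_equal(unname(model@Ni[model@descriptors == d]), sum(inSola))
  expect_equal(unname(model@Nik[model@descriptors == d]),
               sum(inSola & s$positive))

  empty <- new("TrainingSet", reactionClass = "all_reactions",
               negativeType = "type1", molecules = list(),
               solas = data.frame(mol = integer(0), atom = integer(0),
                                  positive = logical(0)),
               provenance = "")
  expect_error(trainClassModel(empty), "untrainable")
})

test_that("B attains its boundary values exactly", {
  # every conditional probability 1 -> B = 1
  m <- mkModel(4, 2, c("a", "b"), Ni = c(2, 1), Nik = c(2, 1))
  expect_identical(bValue(m, c("a", "b")), 1)
  # every conditional probability 0 -> B = -1
  m0 <- mkModel(4, 2, c("a", "b"), Ni = c(2, 1), Nik = c(0, 0))
  expect_identical(bValue(m0, c("a", "b")), -1)
  # P(Tk|Di) = P(Tk) for all descriptors -> B = 0
  mU <- mkModel(4, 2, c("a", "b"), Ni = c(4, 2), Nik = c(2, 1))
  expect_equal(bValue(mU, c("a", "b")), 0)
})

test_that("B matches an independent evaluation of the printed formulas", {
  # m = 2, P(Tk|D1) = 0.9, P(Tk|D2) = 0.5, P(Tk) = 0.25
  m <- mkModel(40, 10, c("d1", "d2"), Ni = c(10, 2), Nik = c(9, 1))
  b <- bValue(m, c("d1", "d2"))
  # independent oracle: direct evaluation with the plain formulas gives
  # (1/sqrt(5) + 1/2) / (1 + 1/(2*sqrt(5))) = 0.7741160
  S <- sin(mean(asin(2 * c(0.9, 0.5) - 1)))
  S0 <- 2 * 0.25 - 1
  expect_equal(b, (S - S0) / (1 - S * S0), tolerance = 1e-12)
  expect_equal(b, 0.7741160, tolerance = 1e-6)
})

test_that("unseen descriptors are skipped; degenerate paths are defined", {
  m <- mkModel(10, 5, c("a"), Ni = 5, Nik = 5)
  expect_equal(bValue(m, c("a", "zz")), bValue(m, "a"))   # zz unknown
  expect_identical(bValue(m, "zz"), 0)                    # all skipped
  # descriptor unique to the excluded SoLA disappears after exclusion
  expect_identical(
    bValue(mkModel(3, 1, "u", 1, 1), "u",
           exclude = list(positive = TRUE, descriptors = "u")), 0)
  expect_error(
    bValue(mkModel(1, 1, "a", 1, 1), "a",
           exclude = list(positive = TRUE, descriptors = "a")),
    "empty training set")
})

test_that("decremental LOO equals scratch retraining on random toy sets", {
  for (sd in 1:20) {
    ts <- toyTrainingSet(sd * 13)
    model <- trainClassModel(ts)
    loo <- looBValues(model, ts)
    s <- solas(ts)
    sets <- metaboRA:::.trainingDescriptorSets(ts)
    # scratch: drop the SoLA, retrain, evaluate its descriptor set
    check <- which(s$positive)[1:2]
    check <- c(check, which(!s$positive)[1:3])
    for (r in check) {
      ts2 <- ts
      ts2@solas <- s[-r, , drop = FALSE]
      if (sum(ts2@solas$positive) == 0 || sum(!ts2@solas$positive) == 0) next
      m2 <- trainClassModel(ts2)
      expect_equal(loo[r], bValue(m2, sets[[r]]), tolerance = 0,
                   label = sprintf("set %d sola %d", sd, r))
    }
  }
})

test_that("LOO distributions sort per polarity and require both sides", {
  ts <- toyTrainingSet(5)
  model <- trainClassModel(ts)
  loo <- looBValues(model, ts)
  d <- fitDistributions(loo, ts)
  expect_false(is.unsorted(d$posB))
  expect_false(is.unsorted(d$negB))
  expect_length(c(d$posB, d$negB), nrow(solas(ts)))
  allPos <- ts; allPos@solas$positive <- TRUE
  expect_error(fitDistributions(loo, allPos), "positive and negative")
  expect_error(fitDistributions(loo[-1], ts), "every SoLA")
})

test_that("Pt/Pf are mid-rank exceedance probabilities", {
  p <- metaboRA:::.ptPf(posB = c(0.2, 0.6), negB = c(0.1, 0.3), b = 0.4)
  expect_equal(p$Pt, 0.5)
  expect_equal(p$Pf, 0)
  hi <- metaboRA:::.ptPf(c(0.2, 0.6), c(0.1, 0.3), b = 0.9)
  expect_equal(hi$Pt - hi$Pf, 1)    # above every training value
  lo <- metaboRA:::.ptPf(c(0.2, 0.6), c(0.1, 0.3), b = -0.9)
  expect_equal(lo$Pt - lo$Pf, -1)
})

test_that("B is monotone in each conditional probability; deltaP in B", {
  set.seed(101)
  for (i in 1:25) {
    nd <- sample(2:6, 1)
    Ni <- sample(2:10, nd, replace = TRUE)
    # Nk chosen above max(Ni) so any Nik <= Ni stays a consistent count
    Nik <- vapply(Ni, function(n) sample(0:(n - 1), 1), 0L)
    N <- 60L; Nk <- 25L
    m <- mkModel(N, Nk, paste0("d", seq_len(nd)), Ni, Nik)
    b0 <- bValue(m, m@descriptors)
    j <- sample(nd, 1)
    bumped <- m@Nik; bumped[j] <- min(m@Ni[j], bumped[j] + 1L)
    m2 <- mkModel(N, Nk, m@descriptors, m@Ni, bumped)
    expect_gte(bValue(m2, m@descriptors), b0 - 1e-12)
  }
  posB <- sort(runif(30, -1, 1)); negB <- sort(runif(40, -1, 1))
  b <- sort(runif(50, -1, 1))
  p <- metaboRA:::.ptPf(posB, negB, b)
  expect_false(is.unsorted(p$Pt - p$Pf))
})

test_that("atom ranking is deterministic, deltaP-ordered and element-filtered", {
  bm <- smallBenchmark()
  ts <- assembleTrainingSet(lapply(bm$records, mapReactionRecord),
                            "O_dealkylation", "type1")
  model <- fitClassModel(ts)
  met <- parseFixture("metoprolol")
  pred <- predictAtoms(model, met, candidateFilter = "class_element")
  expect_true(all(pred$element == "O"))
  expect_equal(pred$rank, seq_len(nrow(pred)))
  expect_false(is.unsorted(-pred$deltaP))
  expect_equal(pred$deltaP, pred$Pt - pred$Pf)
  # ranking by deltaP coincides with ranking by B
  expect_equal(order(-pred$B, pred$atom), order(-pred$deltaP, pred$atom))
  expect_identical(pred, predictAtoms(model, met))
  # a molecule without candidate atoms yields an empty frame, not an error
  none <- predictAtoms(fitClassModel(assembleTrainingSet(
    lapply(bm$records, mapReactionRecord), "S_oxidation", "type1")),
    parseFixture("toluene"))
  expect_equal(nrow(none), 0)
})

test_that("models persist through JSON and reload identically", {
  ts <- toyTrainingSet(9)
  model <- fitClassModel(ts)
  path <- withr::local_tempfile(fileext = ".json")
  writeClassModel(model, path)
  back <- readClassModel(path)
  for (sl in c("reactionClass", "negativeType", "maxLevel", "levelsMode",
               "N", "Nk", "descriptors", "Ni", "Nik", "posB", "negB"))
    expect_equal(slot(back, sl), slot(model, sl), label = sl)
  expect_error(readClassModel(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "not a metaboRA")
})
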
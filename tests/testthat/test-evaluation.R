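test_that("IAP follows the strict pairwise counting formula", {
  expect_equal(iap(c(0.9, 0.8), 0.1), 1.0)
  expect_equal(iap(0.5, 0.5), 0.0)          # strict: ties do not count
  expect_equal(iap(c(0.7, 0.3), 0.5), 0.5)  # one win, one loss
  expect_equal(iap(0.5, 0.5, ties = TRUE), 0.5)
  expect_error(iap(numeric(0), 1), "at least one")
})

test_that("IAP agrees with brute force and the rank-based AUC oracle", {
  set.seed(7)
  for (i in 1:30) {
    np <- sample(1:60, 1); nn <- sample(1:60, 1)
    pos <- sample(round(runif(np, -1, 1), 2))   # rounding forces ties
    neg <- sample(round(runif(nn, -1, 1), 2))
    brute <- sum(outer(pos, neg, ">")) / (np * nn)
    expect_equal(iap(pos, neg), brute)
    w <- suppressWarnings(wilcox.test(pos, neg))$statistic / (np * nn)
    expect_equal(iap(pos, neg, ties = TRUE), unname(w))
    expect_lte(iap(pos, neg), iap(pos, neg, ties = TRUE))
  }
})

test_that("IAP is invariant under strictly monotone score transforms", {
  set.seed(11)
  pos <- runif(40); neg <- runif(50)
  for (f in list(function(x) 3 * x - 2, function(x) x^3, tanh))
    expect_equal(iap(f(pos), f(neg)), iap(pos, neg))
})

test_that("shuffled labels give chance-level tie-aware IAP", {
  set.seed(3)
  x <- rnorm(4000)
  lab <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  se <- sqrt((4000 + 1) / (12 * sum(lab) * sum(!lab)))
  expect_lt(abs(iap(x[lab], x[!lab], ties = TRUE) - 0.5), 3 * se)
})

test_that("Top-k counts a molecule as correct when a true atom ranks <= k", {
  pred <- data.frame(atom = c(5, 2, 9, 1), rank = 1:4)
  expect_true(topKSuccess(pred, 5, 1))
  expect_false(topKSuccess(pred, 2, 1))
  expect_true(topKSuccess(pred, 2, 2))
  expect_false(topKSuccess(pred, 1, 3))
  expect_true(topKSuccess(pred, c(8, 9), 3))
  expect_error(topKSuccess(pred, integer(0), 1), "cannot be scored")
})

test_that("cross-validation is deterministic and partitions by molecule", {
  bm <- smallBenchmark()
  records <- lapply(bm$records, mapReactionRecord)
  ts <- assembleTrainingSet(records, "O_dealkylation", "type1")
  a <- crossValidate(ts, "kfold", k = 5, seed = 99)
  b <- crossValidate(ts, "kfold", k = 5, seed = 99)
  expect_identical(a, b)
  expect_true(a$top1 <= a$top2 && a$top2 <= a$top3)
  expect_true(a$iap >= 0 && a$iap <= 1)

  nMol <- length(trainingMolecules(ts))
  expect_error(crossValidate(ts, "kfold", k = nMol + 1), "between 2 and")
  # k = number of molecules degenerates to leave-one-molecule-out
  lomo <- crossValidate(ts, "kfold", k = nMol, seed = 1)
  expect_false(anyNA(lomo$iap))
})

test_that("LOO and k-fold cross-validation agree on a learnable class", {
  bm <- smallBenchmark()
  records <- lapply(bm$records, mapReactionRecord)
  cache <- newDescriptorCache()
  ts <- assembleTrainingSet(records, "O_dealkylation", "type1")
  loo <- crossValidate(ts, "loo", cache = cache)
  kf <- crossValidate(ts, "kfold", k = 10, seed = 42, cache = cache)
  expect_lt(abs(loo$iap - kf$iap), 0.03)
  expect_gt(loo$iap_tie, 0.95)
})
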
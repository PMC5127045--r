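## Validation metrics and cross-validation.
##
## IAP (invariant accuracy of prediction) is the probability that a random
## positive example scores a higher deltaP than a random negative one:
## NumOf{deltaP+ > deltaP-} / (N+ * N-), counting strict inequalities. The
## tie-aware variant credits ties 0.5 and equals the Mann-Whitney AUC.

# counts of v (sorted) strictly below / at each x
.countLess <- function(vSorted, x) findInterval(x, vSorted, left.open = TRUE)
.countLeq  <- function(vSorted, x) findInterval(x, vSorted)

#' Invariant accuracy of prediction (IAP)
#'
#' @param posScores deltaP (or any monotone score) of positive examples.
#' @param negScores scores of negative examples.
#' @param ties if `TRUE`, ties count 0.5 (Mann-Whitney AUC); the default
#'   counts only strict inequalities.
#' @return IAP in `[0, 1]`.
#' @export
iap <- function(posScores, negScores, ties = FALSE) {
  if (length(posScores) == 0L || length(negScores) == 0L)
    stop("need at least one positive and one negative score")
  ns <- sort(negScores)
  lt <- .countLess(ns, posScores)
  if (!ties) return(sum(lt) / (length(posScores) * length(negScores)))
  eq <- .countLeq(ns, posScores) - lt
  (sum(lt) + 0.5 * sum(eq)) / (length(posScores) * length(negScores))
}

#' Top-k success of a ranked atom prediction for one molecule
#'
#' A molecule is correctly predicted at level k when any experimental
#' reacting atom is ranked within the top k positions.
#'
#' @param predictions ranked data.frame from [predictAtoms()].
#' @param trueAtoms nonempty set of experimental reacting-atom indices.
#' @param k rank cutoff (1, 2, 3, or any positive integer).
#' @return logical scalar.
#' @export
topKSuccess <- function(predictions, trueAtoms, k) {
  if (length(trueAtoms) == 0L)
    stop("no experimental reacting atoms; molecule cannot be scored")
  hit <- predictions$rank[predictions$atom %in% trueAtoms]
  length(hit) > 0L && any(hit <= k)
}

# deltaP of training SoLAs against leave-self-out LOO distributions
.looDeltaP <- function(loo, positive) {
  posS <- sort(loo[positive]); negS <- sort(loo[!positive])
  np <- length(posS); nn <- length(negS)
  lt <- .countLess(posS, loo); eqp <- .countLeq(posS, loo) - lt
  gt <- nn - .countLeq(negS, loo); eqn <- .countLeq(negS, loo) -
    .countLess(negS, loo)
  # drop each SoLA's own value from its side
  ownP <- as.numeric(positive); ownN <- as.numeric(!positive)
  pt <- (lt + 0.5 * (eqp - ownP)) / (np - ownP)
  pf <- (gt + 0.5 * (eqn - ownN)) / (nn - ownN)
  pt - pf
}

# per-molecule Top-k from per-SoLA deltaP scores
.topkFromScores <- function(solasDf, deltaP) {
  res <- c(top1 = NA_real_, top2 = NA_real_, top3 = NA_real_)
  byMol <- split(seq_len(nrow(solasDf)), solasDf$mol)
  hits <- matrix(NA, nrow = length(byMol), ncol = 3)
  j <- 0L
  for (rows in byMol) {
    if (!any(solasDf$positive[rows])) next
    j <- j + 1L
    ord <- rows[order(-deltaP[rows], solasDf$atom[rows])]
    rk <- match(TRUE, solasDf$positive[ord])
    hits[j, ] <- rk <= 1:3
  }
  if (j > 0L) res <- colMeans(hits[seq_len(j), , drop = FALSE])
  names(res) <- c("top1", "top2", "top3")
  res
}

.evalReport <- function(class, negType, mode, k, seed, pos, dP, nMol) {
  tk <- .topkFromScores
  data.frame(
    reaction_class = class, negative_type = negType, cv_mode = mode,
    k = if (is.null(k)) NA_integer_ else k,
    seed = if (is.null(seed)) NA_integer_ else seed,
    n_pos = sum(pos), n_neg = sum(!pos), n_molecules = nMol,
    iap = iap(dP[pos], dP[!pos]),
    iap_tie = iap(dP[pos], dP[!pos], ties = TRUE),
    stringsAsFactors = FALSE)
}

#' Cross-validate a training set
#'
#' `"loo"` excludes one SoLA at a time (decremental counts) and scores it
#' against the leave-one-out B distributions of the remaining SoLAs.
#' `"kfold"` partitions at the molecule level — all SoLAs of a molecule
#' fall in one fold, so shared descriptors cannot leak — then fits counts
#' and LOO distributions on the training folds and pools the held-out
#' deltaP values. Top-k rates are computed per molecule over its own
#' candidate SoLAs.
#'
#' @param trainingSet a [TrainingSet-class].
#' @param mode `"loo"` or `"kfold"`.
#' @param k number of folds (kfold only); must not exceed the number of
#'   molecules.
#' @param seed integer seed controlling the fold assignment.
#' @param maxLevel,levelsMode,cache descriptor configuration.
#' @return one-row data.frame: class, mode, IAP (strict and tie-aware),
#'   Top-1/2/3, counts and seed.
#' @export
crossValidate <- function(trainingSet, mode = c("loo", "kfold"), k = 20L,
                          seed = 1L, maxLevel = 2L, levelsMode = "upto",
                          cache = NULL) {
  mode <- match.arg(mode)
  s <- trainingSet@solas
  pos <- s$positive
  if (mode == "loo") {
    model <- trainClassModel(trainingSet, maxLevel, levelsMode, cache)
    loo <- looBValues(model, trainingSet, cache = cache)
    dP <- .looDeltaP(loo, pos)
    rep <- .evalReport(trainingSet@reactionClass, trainingSet@negativeType,
                       "loo", NULL, NULL, pos, dP, length(trainingSet@molecules))
  } else {
    nMol <- length(trainingSet@molecules)
    if (k < 2L || k > nMol)
      stop("k must be between 2 and the number of molecules (", nMol, ")")
    fold <- .withSeed(seed, sample(rep_len(seq_len(k), nMol)))
    model0 <- trainClassModel(trainingSet, maxLevel, levelsMode, cache)
    idx <- attr(model0, "solaIndex")
    dP <- rep(NA_real_, nrow(s))
    for (f in seq_len(k)) {
      testRows <- which(fold[s$mol] == f)
      trainRows <- setdiff(seq_len(nrow(s)), testRows)
      if (sum(pos[trainRows]) == 0L || sum(!pos[trainRows]) == 0L)
        stop("fold ", f, " leaves an untrainable training portion")
      Ni <- tabulate(unlist(idx[trainRows]), nbins = length(model0@descriptors))
      Nik <- tabulate(unlist(idx[trainRows][pos[trainRows]]),
                      nbins = length(model0@descriptors))
      mF <- new("ClassModel",
        reactionClass = model0@reactionClass, negativeType = model0@negativeType,
        maxLevel = model0@maxLevel, levelsMode = model0@levelsMode,
        grammar = model0@grammar,
        N = length(trainRows), Nk = sum(pos[trainRows]),
        descriptors = model0@descriptors, Ni = Ni, Nik = Nik,
        posB = numeric(0), negB = numeric(0))
      looF <- vapply(trainRows, function(r) {
        i <- idx[[r]]
        p <- pos[r]
        .bCore(mF@N - 1L, mF@Nk - (if (p) 1L else 0L),
               Ni[i] - 1L, Nik[i] - (if (p) 1L else 0L))
      }, numeric(1))
      posS <- sort(looF[pos[trainRows]]); negS <- sort(looF[!pos[trainRows]])
      bTest <- vapply(testRows, function(r) {
        i <- idx[[r]]
        .bCore(mF@N, mF@Nk, Ni[i], Nik[i])
      }, numeric(1))
      p <- .ptPf(posS, negS, bTest)
      dP[testRows] <- p$Pt - p$Pf
    }
    rep <- .evalReport(trainingSet@reactionClass, trainingSet@negativeType,
                       "kfold", k, seed, pos, dP, nMol)
  }
  tk <- .topkFromScores(s, dP)
  rep$top1 <- tk["top1"]; rep$top2 <- tk["top2"]; rep$top3 <- tk["top3"]
  rownames(rep) <- NULL
  rep
}
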
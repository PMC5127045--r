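## Bayesian-like atom scoring.
##
## From a trained count table the B statistic of a SoLA with descriptors
## D_1..D_m is
##     B = (S - S0) / (1 - S * S0)
##     S  = sin( mean( asin(2 * P(Tk|Di) - 1) ) )
##     S0 = 2 * P(Tk) - 1
## with the raw frequency estimates P(Tk) = Nk/N and P(Tk|Di) = Nik/Ni.
## No smoothing is applied; descriptors unseen in the (possibly
## LOO-decremented) training counts are skipped, and when every descriptor
## is skipped the information-free score B = 0 is returned. Pt and Pf are
## mid-rank empirical exceedance probabilities over the leave-one-out B
## distributions of the positive and negative training examples.

.clamp <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

# core B computation from adjusted counts
.bCore <- function(N, Nk, ni, nik) {
  if (N <= 0L) stop("empty training set after exclusion")
  keep <- ni > 0L
  ni <- ni[keep]; nik <- nik[keep]
  if (length(ni) == 0L) return(0)
  s <- sin(mean(asin(.clamp(2 * nik / ni - 1))))
  s0 <- 2 * Nk / N - 1
  denom <- 1 - s * s0
  if (abs(denom) < 1e-12) return(0)
  .clamp((s - s0) / denom)
}

#' Train the count tables of a class model
#'
#' Counts `N`, `Nk` and per-descriptor `Ni`, `Nik` over the training set's
#' SoLAs; descriptor sets are computed once per molecule.
#'
#' @param trainingSet a [TrainingSet-class] with at least one positive and
#'   one negative SoLA.
#' @param maxLevel,levelsMode descriptor configuration (see [lmnaSet()]).
#' @param cache optional [newDescriptorCache()] environment.
#' @return a [ClassModel-class] without score distributions (see
#'   [fitClassModel()] for the full training pipeline).
#' @export
trainClassModel <- function(trainingSet, maxLevel = 2L, levelsMode = "upto",
                            cache = NULL) {
  s <- trainingSet@solas
  if (nrow(s) == 0L || sum(s$positive) == 0L || sum(!s$positive) == 0L)
    stop("untrainable set: need at least one positive and one negative SoLA")
  sets <- .trainingDescriptorSets(trainingSet, maxLevel, levelsMode, cache)
  descriptors <- sort(unique(unlist(sets)), method = "radix")
  idx <- utils::relist(match(unlist(sets), descriptors), sets)
  model <- new("ClassModel",
    reactionClass = trainingSet@reactionClass,
    negativeType  = trainingSet@negativeType,
    maxLevel = as.integer(maxLevel), levelsMode = levelsMode,
    grammar = .LMNA_GRAMMAR,
    N = nrow(s), Nk = sum(s$positive),
    descriptors = descriptors,
    Ni  = tabulate(unlist(idx), nbins = length(descriptors)),
    Nik = tabulate(unlist(idx[s$positive]), nbins = length(descriptors)),
    posB = numeric(0), negB = numeric(0))
  attr(model, "solaIndex") <- idx
  model
}

#' B statistic of a descriptor set under a trained model
#'
#' @param model a [ClassModel-class].
#' @param descriptors character vector of LMNA descriptors (a SoLA's set).
#' @param exclude optional leave-one-out exclusion: a list with elements
#'   `positive` (logical) and `descriptors` (the excluded SoLA's set); its
#'   contributions are decremented from the counts before evaluation.
#' @return B in `[-1, 1]`.
#' @export
bValue <- function(model, descriptors, exclude = NULL) {
  i <- match(descriptors, model@descriptors)
  found <- !is.na(i)
  ni <- model@Ni[i[found]]
  nik <- model@Nik[i[found]]
  N <- model@N; Nk <- model@Nk
  if (!is.null(exclude)) {
    N <- N - 1L
    if (isTRUE(exclude$positive)) Nk <- Nk - 1L
    j <- match(descriptors[found], exclude$descriptors)
    dec <- !is.na(j)
    ni[dec] <- ni[dec] - 1L
    if (isTRUE(exclude$positive)) nik[dec] <- nik[dec] - 1L
  }
  .bCore(N, Nk, ni, nik)
}

#' Leave-one-out B values of every training SoLA
#'
#' Each SoLA's own contributions (1 from `N`, possibly `Nk`, and one from
#' `Ni`/`Nik` of each of its descriptors) are decremented before its B is
#' evaluated — exactly equivalent to retraining without that SoLA, at
#' integer-count precision.
#'
#' @param model the [ClassModel-class] trained on exactly `trainingSet`.
#' @param trainingSet the training set.
#' @param maxLevel,levelsMode,cache descriptor configuration, as in
#'   [trainClassModel()].
#' @return numeric vector of LOO B values aligned with
#'   `solas(trainingSet)` rows.
#' @export
looBValues <- function(model, trainingSet, maxLevel = model@maxLevel,
                       levelsMode = model@levelsMode, cache = NULL) {
  idx <- attr(model, "solaIndex")
  if (is.null(idx)) {
    sets <- .trainingDescriptorSets(trainingSet, maxLevel, levelsMode, cache)
    idx <- utils::relist(match(unlist(sets), model@descriptors), sets)
  }
  s <- trainingSet@solas
  vapply(seq_len(nrow(s)), function(r) {
    i <- idx[[r]]
    pos <- s$positive[r]
    ni <- model@Ni[i] - 1L
    nik <- model@Nik[i] - (if (pos) 1L else 0L)
    .bCore(model@N - 1L, model@Nk - (if (pos) 1L else 0L), ni, nik)
  }, numeric(1))
}

#' Fit the Pt/Pf score distributions from leave-one-out B values
#'
#' @param looB numeric vector of LOO B values aligned with the training
#'   set's SoLAs.
#' @param trainingSet the training set.
#' @return list with sorted `posB` and `negB`.
#' @export
fitDistributions <- function(looB, trainingSet) {
  pos <- trainingSet@solas$positive
  if (length(looB) != length(pos))
    stop("looB must cover every SoLA of the training set")
  if (!any(pos) || all(pos))
    stop("need both positive and negative examples to fit distributions")
  list(posB = sort(looB[pos]), negB = sort(looB[!pos]))
}

#' Full training pipeline: counts, LOO B values, score distributions
#'
#' @inheritParams trainClassModel
#' @return a complete [ClassModel-class] (with `posB`/`negB` populated).
#' @export
fitClassModel <- function(trainingSet, maxLevel = 2L, levelsMode = "upto",
                          cache = NULL) {
  model <- trainClassModel(trainingSet, maxLevel, levelsMode, cache)
  loo <- looBValues(model, trainingSet, cache = cache)
  d <- fitDistributions(loo, trainingSet)
  model@posB <- d$posB
  model@negB <- d$negB
  attr(model, "looB") <- loo
  model
}

# mid-rank exceedance probabilities; b may be a vector
.ptPf <- function(posB, negB, b) {
  pt <- vapply(b, function(x)
    (sum(posB < x) + 0.5 * sum(posB == x)) / length(posB), numeric(1))
  pf <- vapply(b, function(x)
    (sum(negB > x) + 0.5 * sum(negB == x)) / length(negB), numeric(1))
  list(Pt = pt, Pf = pf)
}

#' Rank the atoms of a molecule by probability of being the reacting atom
#'
#' Generates one SoLA per candidate atom, scores it with the model's B
#' statistic, reads `Pt` and `Pf` from the model's leave-one-out score
#' distributions (mid-rank estimator) and ranks by non-increasing
#' `deltaP = Pt - Pf` (ties broken by ascending atom index).
#'
#' @param model a fully fitted [ClassModel-class].
#' @param molecule a [MolecularGraph-class].
#' @param candidateFilter `"class_element"` (atoms of the class's
#'   characteristic element; the default) or `"all_heavy"`.
#' @return data.frame with columns `atom`, `element`, `B`, `Pt`, `Pf`,
#'   `deltaP`, `rank`, ordered by rank; zero rows when the molecule has no
#'   candidate atoms.
#' @export
predictAtoms <- function(model, molecule,
                         candidateFilter = c("class_element", "all_heavy")) {
  candidateFilter <- match.arg(candidateFilter)
  if (length(model@posB) == 0L || length(model@negB) == 0L)
    stop("model has no score distributions; use fitClassModel()")
  cand <- heavyAtoms(molecule)
  elem <- classElement(model@reactionClass)
  if (candidateFilter == "class_element" && !is.na(elem))
    cand <- cand[molecule@atoms$element[cand] == elem]
  if (length(cand) == 0L)
    return(data.frame(atom = integer(0), element = character(0),
                      B = numeric(0), Pt = numeric(0), Pf = numeric(0),
                      deltaP = numeric(0), rank = integer(0)))
  sets <- solaDescriptorSets(molecule, cand, model@maxLevel, model@levelsMode)
  b <- vapply(sets, function(d) bValue(model, d), numeric(1))
  p <- .ptPf(model@posB, model@negB, b)
  dP <- p$Pt - p$Pf
  ord <- order(-dP, cand)
  out <- data.frame(atom = cand, element = molecule@atoms$element[cand],
                    B = b, Pt = p$Pt, Pf = p$Pf, deltaP = dP,
                    rank = NA_integer_)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Model persistence (versioned JSON)
## ---------------------------------------------------------------------------

.MODEL_FORMAT <- "metaboRA-classmodel/1"

#' Write a class model to a self-describing JSON file
#'
#' The file carries the counts, the descriptor configuration and both LOO
#' B arrays, so prediction needs no training data.
#'
#' @param model a [ClassModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClassModel <- function(model, path) {
  obj <- list(
    format = .MODEL_FORMAT,
    class = model@reactionClass,
    negative_type = model@negativeType,
    descriptor_config = list(max_level = model@maxLevel,
                             levels_mode = model@levelsMode,
                             grammar = model@grammar),
    N = model@N, N_k = model@Nk,
    descriptor_table = data.frame(d = model@descriptors,
                                  N_i = model@Ni, N_ik = model@Nik),
    pos_b = model@posB, neg_b = model@negB)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a class model written by [writeClassModel()]
#'
#' @param path JSON file path.
#' @return a [ClassModel-class].
#' @export
readClassModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, .MODEL_FORMAT))
    stop("not a metaboRA class-model file: ", path)
  dt <- obj$descriptor_table
  new("ClassModel",
      reactionClass = obj$class, negativeType = obj$negative_type,
      maxLevel = as.integer(obj$descriptor_config$max_level),
      levelsMode = obj$descriptor_config$levels_mode,
      grammar = obj$descriptor_config$grammar,
      N = as.integer(obj$N), Nk = as.integer(obj$N_k),
      descriptors = as.character(dt$d),
      Ni = as.integer(dt$N_i), Nik = as.integer(dt$N_ik),
      posB = as.numeric(obj$pos_b), negB = as.numeric(obj$neg_b))
}
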
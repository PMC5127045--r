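## Training-set assembly: structures with one labelled atom (SoLAs).
##
## A SoLA is a molecule plus one labelled heavy atom; it is positive for a
## reaction class when the labelled atom is a known reacting atom of that
## class. Two negative-example schemes exist: type 1 labels every heavy
## atom, type 2 only atoms of the class's characteristic element.

#' Generate the SoLAs of one molecule for one reaction class
#'
#' @param molecule a [MolecularGraph-class].
#' @param positiveAtoms heavy-atom indices known to react (may be empty).
#' @param reactionClass the reaction class.
#' @param negativeType `"type1"`: one SoLA per heavy atom; `"type2"`: one
#'   SoLA per heavy atom of the class's characteristic element.
#' @return data.frame with columns `atom`, `element`, `positive`,
#'   `negative_type`, ordered by atom index.
#' @export
buildSolas <- function(molecule, positiveAtoms, reactionClass,
                       negativeType = c("type1", "type2")) {
  negativeType <- match.arg(negativeType)
  .checkClass(reactionClass)
  positiveAtoms <- as.integer(positiveAtoms)
  hv <- heavyAtoms(molecule)
  if (length(positiveAtoms) && !all(positiveAtoms %in% hv))
    stop("positive atoms must be heavy atoms of the molecule")
  elem <- classElement(reactionClass)
  if (length(positiveAtoms) && !is.na(elem) &&
      !all(molecule@atoms$element[positiveAtoms] == elem))
    stop(sprintf(
      "data-consistency error: positive atom element does not match class %s (%s)",
      reactionClass, elem))
  cand <- hv
  if (negativeType == "type2" && !is.na(elem))
    cand <- hv[molecule@atoms$element[hv] == elem]
  data.frame(
    atom = cand,
    element = molecule@atoms$element[cand],
    positive = cand %in% positiveAtoms,
    negative_type = rep(negativeType, length(cand)),
    stringsAsFactors = FALSE)
}

#' Assemble the training set of a reaction class from mapped records
#'
#' Substrates are deduplicated by canonical structure; a substrate
#' appearing in several records contributes once, with the union of the
#' reacting atoms of its records whose class belongs to `reactionClass`
#' (merged classes union their members). Substrates whose records all
#' belong to other classes still contribute all-negative SoLAs.
#'
#' @param records list of [ReactionRecord-class]; unmapped records are
#'   mapped first.
#' @param reactionClass class to assemble (may be merged, e.g.
#'   `"hydroxylation"`).
#' @param negativeType `"type1"` or `"type2"`.
#' @param provenance free-text source description.
#' @return a [TrainingSet-class].
#' @export
assembleTrainingSet <- function(records, reactionClass,
                                negativeType = c("type1", "type2"),
                                provenance = "reaction records") {
  negativeType <- match.arg(negativeType)
  .checkClass(reactionClass)
  members <- classMembers(reactionClass)
  records <- lapply(records, function(r)
    if (is.null(r@mapping)) mapReactionRecord(r) else r)

  subs <- lapply(records, slot, "substrate")
  # identity key: element sequence + bond table (merges repeated records of
  # one substrate parsed from the same input, the case Table-2-style counts
  # rely on; differently ordered duplicates stay separate)
  keys <- vapply(subs, function(g) paste(
    paste(g@atoms$element, collapse = ""),
    paste(g@bonds$a1, g@bonds$a2, g@bonds$order, collapse = ";"),
    sep = "|"), "")
  uk <- unique(keys)
  molecules <- subs[match(uk, keys)]

  posList <- replicate(length(uk), integer(0), simplify = FALSE)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.na(r@assignedClass) || !r@assignedClass %in% members) next
    k <- match(keys[i], uk)
    posList[[k]] <- union(posList[[k]], r@mapping@reactingAtoms)
  }
  if (sum(lengths(posList)) == 0)
    stop(sprintf("untrainable class '%s': no positive examples", reactionClass))

  tabs <- lapply(seq_along(molecules), function(k) {
    s <- buildSolas(molecules[[k]], posList[[k]], reactionClass, negativeType)
    if (nrow(s)) s$mol <- k
    s
  })
  solas <- do.call(rbind, tabs[vapply(tabs, nrow, 0L) > 0])
  solas <- solas[order(solas$mol, solas$atom),
                 c("mol", "atom", "element", "positive", "negative_type")]
  rownames(solas) <- NULL
  new("TrainingSet", reactionClass = reactionClass,
      negativeType = negativeType, molecules = molecules,
      solas = solas, provenance = provenance)
}

#' Write a training set as TSV
#'
#' Columns: canonical structure string, atom number (1-based), class,
#' polarity, negative_type.
#'
#' @param trainingSet a [TrainingSet-class].
#' @param file output path, or `NULL` to return the data.frame.
#' @return the data.frame, invisibly when written.
#' @export
writeTrainingSet <- function(trainingSet, file = NULL) {
  smi <- canonicalSmiles(trainingSet@molecules)
  s <- trainingSet@solas
  df <- data.frame(
    structure = smi[s$mol],
    atom = s$atom,
    class = trainingSet@reactionClass,
    polarity = ifelse(s$positive, "positive", "negative"),
    negative_type = s$negative_type,
    stringsAsFactors = FALSE)
  if (is.null(file)) return(df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
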
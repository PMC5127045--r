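#' @import methods
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Reaction-class vocabulary
## ---------------------------------------------------------------------------

.ELEMENTARY_CLASSES <- c(
  aliphatic_hydroxylation = "C",
  aromatic_hydroxylation  = "C",
  C_oxidation             = "C",
  N_glucuronidation       = "N",
  N_oxidation             = "N",
  N_dealkylation          = "N",
  O_glucuronidation       = "O",
  O_dealkylation          = "O",
  S_oxidation             = "S"
)

.MERGED_CLASSES <- c("hydroxylation", "all_cyp_reactions", "all_reactions")

.CYP_CLASSES <- c("aliphatic_hydroxylation", "aromatic_hydroxylation",
                  "C_oxidation", "N_oxidation", "S_oxidation",
                  "N_dealkylation", "O_dealkylation")

.GLUC_CLASSES <- c("N_glucuronidation", "O_glucuronidation")

.CYP_FAMILIES <- c("CYP1A2", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A4")

#' Reaction class vocabulary
#'
#' The nine elementary biotransformation classes plus the three merged
#' classes (`hydroxylation`, `all_cyp_reactions`, `all_reactions`).
#'
#' @param merged include the merged classes.
#' @return character vector of class names.
#' @export
reactionClasses <- function(merged = FALSE) {
  cls <- names(.ELEMENTARY_CLASSES)
  if (merged) cls <- c(cls, .MERGED_CLASSES)
  cls
}

.checkClass <- function(reactionClass) {
  if (!is.character(reactionClass) || length(reactionClass) != 1L ||
      !reactionClass %in% reactionClasses(merged = TRUE))
    stop("unknown reaction class: ", paste(reactionClass, collapse = ", "))
  reactionClass
}

#' Characteristic element of a reaction class
#'
#' The nine elementary classes each act on one element (C, N, O or S);
#' `hydroxylation` acts on C. The fully merged classes have no
#' characteristic element and return `NA`.
#'
#' @param reactionClass a reaction class name.
#' @return single character element symbol or `NA`.
#' @export
classElement <- function(reactionClass) {
  .checkClass(reactionClass)
  if (reactionClass %in% names(.ELEMENTARY_CLASSES))
    return(unname(.ELEMENTARY_CLASSES[reactionClass]))
  if (reactionClass == "hydroxylation") return("C")
  NA_character_
}

#' Elementary members of a (possibly merged) reaction class
#'
#' @param reactionClass a reaction class name.
#' @return character vector of elementary class names.
#' @export
classMembers <- function(reactionClass) {
  .checkClass(reactionClass)
  switch(reactionClass,
    hydroxylation     = c("aliphatic_hydroxylation", "aromatic_hydroxylation"),
    all_cyp_reactions = .CYP_CLASSES,
    all_reactions     = names(.ELEMENTARY_CLASSES),
    reactionClass)
}

#' Normalize an enzyme annotation to the closed vocabulary
#'
#' Maps free-text enzyme labels onto `CYP1A2`, `CYP2C19`, `CYP2C9`,
#' `CYP2D6`, `CYP3A4`, `UGT` or `other`. Any UGT isoform label (e.g.
#' `UGT1A1`) collapses to `UGT`; unknown labels map to `other`.
#'
#' @param label character vector of enzyme labels.
#' @return character vector in the closed vocabulary.
#' @export
normalizeEnzyme <- function(label) {
  out <- rep("other", length(label))
  lab <- toupper(trimws(as.character(label)))
  for (fam in .CYP_FAMILIES) out[lab == fam] <- fam
  out[startsWith(lab, "UGT")] <- "UGT"
  out[is.na(label)] <- "other"
  out
}

## ---------------------------------------------------------------------------
## MolecularGraph
## ---------------------------------------------------------------------------

#' MolecularGraph: hydrogen-explicit chemical graph
#'
#' Atoms are rows of the `atoms` data.frame (columns `element`, `aromatic`,
#' `ring`, `charge`, `hydrogen`); bonds are rows of `bonds`
#' (`a1`, `a2`, `order`, with order 4 denoting an aromatic bond). All atom
#' indices are 1-based, heavy atoms come first in input order with explicit
#' hydrogens appended.
#'
#' @slot atoms data.frame of per-atom attributes.
#' @slot bonds data.frame of bonds.
#' @slot name molecule name.
#' @slot source original input string (or a short provenance tag).
#' @export
setClass("MolecularGraph", representation(
  atoms  = "data.frame",
  bonds  = "data.frame",
  name   = "character",
  source = "character"
))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  need <- c("element", "aromatic", "ring", "charge", "hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(b) > 0) {
    if (!all(c("a1", "a2", "order") %in% names(b)))
      return("bonds must have columns a1, a2, order")
    if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
      return("bond endpoint out of range")
    if (any(b$a1 == b$a2)) return("self-bond")
  }
  TRUE
})

#' @describeIn MolecularGraph-accessors atom attribute table
#' @export
atoms <- function(x) x@atoms

#' @describeIn MolecularGraph-accessors bond table
#' @export
bonds <- function(x) x@bonds

#' Accessors for MolecularGraph
#'
#' @param x a `MolecularGraph`.
#' @name MolecularGraph-accessors
NULL

#' @describeIn MolecularGraph-accessors molecule name
#' @export
molName <- function(x) x@name

#' @describeIn MolecularGraph-accessors number of non-hydrogen atoms
#' @export
heavyAtomCount <- function(x) sum(!x@atoms$hydrogen)

#' @describeIn MolecularGraph-accessors indices of non-hydrogen atoms
#' @export
heavyAtoms <- function(x) which(!x@atoms$hydrogen)

setMethod("show", "MolecularGraph", function(object) {
  a <- object@atoms
  hv <- a$element[!a$hydrogen]
  comp <- paste(sprintf("%s%d", names(table(hv)), as.integer(table(hv))),
                collapse = " ")
  cat(sprintf("MolecularGraph '%s': %d heavy atoms (%s), %d total, %d bonds\n",
              object@name, sum(!a$hydrogen), comp, nrow(a),
              nrow(object@bonds)))
})

## internal helpers -----------------------------------------------------------

# neighbor list over all atoms (hydrogens included)
.adjacency <- function(g) {
  n <- nrow(g@atoms)
  adj <- vector("list", n)
  b <- g@bonds
  if (nrow(b) > 0) {
    ends <- c(b$a1, b$a2)
    other <- c(b$a2, b$a1)
    sp <- split(other, factor(ends, levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  adj
}

# hydrogen neighbour count per atom
.hCounts <- function(g, adj = .adjacency(g)) {
  ish <- g@atoms$hydrogen
  vapply(adj, function(nb) sum(ish[nb]), integer(1))
}

# heavy-neighbour count per atom
.heavyDegree <- function(g, adj = .adjacency(g)) {
  ish <- g@atoms$hydrogen
  vapply(adj, function(nb) sum(!ish[nb]), integer(1))
}

# igraph of the heavy-atom skeleton; vertex attribute `orig` maps back
.heavySkeleton <- function(g) {
  hv <- which(!g@atoms$hydrogen)
  b <- g@bonds
  keep <- b$a1 %in% hv & b$a2 %in% hv
  idx <- match(seq_len(nrow(g@atoms)), hv)
  ig <- igraph::make_empty_graph(n = length(hv), directed = FALSE)
  if (any(keep))
    ig <- igraph::add_edges(ig, rbind(idx[b$a1[keep]], idx[b$a2[keep]]))
  igraph::V(ig)$element <- g@atoms$element[hv]
  igraph::V(ig)$orig <- hv
  ig
}

# ring membership: an atom is in a ring iff incident to a cycle edge
.ringFlags <- function(nAtoms, bonds) {
  flags <- rep(FALSE, nAtoms)
  if (nrow(bonds) == 0) return(flags)
  ig <- igraph::make_empty_graph(n = nAtoms, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(bonds$a1, bonds$a2))
  br <- igraph::bridges(ig)
  cyc <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  flags[unique(c(bonds$a1[cyc], bonds$a2[cyc]))] <- TRUE
  flags
}

.newMolecularGraph <- function(atoms, bonds, name = "", source = "") {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  atoms$ring <- .ringFlags(nrow(atoms), bonds)
  new("MolecularGraph", atoms = atoms, bonds = bonds,
      name = as.character(name), source = as.character(source))
}

## ---------------------------------------------------------------------------
## ReactionMapping
## ---------------------------------------------------------------------------

#' ReactionMapping: result of substrate/product comparison
#'
#' @slot direction `"addition"`, `"removal"` or `"none"`.
#' @slot embedding representative atom-index map from the smaller heavy-atom
#'   skeleton into the larger (names: smaller-graph indices).
#' @slot reactingAtoms substrate heavy-atom indices whose neighbourhood
#'   changed (union over all surviving embeddings).
#' @slot changedFragment heavy-atom indices of the larger graph outside the
#'   embedding image.
#' @slot fragmentConnected whether the graph difference is connected.
#' @slot nEmbeddings number of surviving embeddings.
#' @export
setClass("ReactionMapping", representation(
  direction         = "character",
  embedding         = "integer",
  reactingAtoms     = "integer",
  changedFragment   = "integer",
  fragmentConnected = "logical",
  nEmbeddings       = "integer"
))

setValidity("ReactionMapping", function(object) {
  if (!object@direction %in% c("addition", "removal", "none"))
    return("direction must be addition, removal or none")
  if (object@direction != "none" && object@fragmentConnected &&
      length(object@changedFragment) == 0)
    return("changed fragment must be nonempty when direction != none")
  TRUE
})

#' @describeIn ReactionMapping-accessors reacting substrate atom indices
#' @export
reactingAtoms <- function(x) x@reactingAtoms

#' Accessors for ReactionMapping
#' @param x a `ReactionMapping`.
#' @name ReactionMapping-accessors
NULL

#' @describeIn ReactionMapping-accessors reaction direction
#' @export
mappingDirection <- function(x) x@direction

#' @describeIn ReactionMapping-accessors atoms of the larger graph absent
#'   from the embedding
#' @export
changedFragment <- function(x) x@changedFragment

setMethod("show", "ReactionMapping", function(object) {
  cat(sprintf(
    "ReactionMapping: direction=%s, reacting atoms={%s}, fragment size=%d%s\n",
    object@direction, paste(object@reactingAtoms, collapse = ","),
    length(object@changedFragment),
    if (object@fragmentConnected) "" else " (disconnected)"))
})

## ---------------------------------------------------------------------------
## ReactionRecord
## ---------------------------------------------------------------------------

#' ReactionRecord: one substrate/product pair
#'
#' @slot substrate,product `MolecularGraph` objects.
#' @slot enzyme enzyme family from the closed vocabulary.
#' @slot declaredClass reaction class annotated in the source (or `NA`).
#' @slot assignedClass class assigned by [assignReactionClass()] (or `NA`).
#' @slot mapping a `ReactionMapping`, or `NULL` before mapping.
#' @slot trueAtom ground-truth reacting atom for synthetic records (`NA`
#'   for real data).
#' @slot consistent `FALSE` when declared and assigned class disagree.
#' @export
setClass("ReactionRecord", representation(
  substrate     = "MolecularGraph",
  product       = "MolecularGraph",
  enzyme        = "character",
  declaredClass = "character",
  assignedClass = "character",
  mapping       = "ANY",
  trueAtom      = "integer",
  consistent    = "logical"
))

#' Construct a reaction record
#'
#' @param substrate,product [MolecularGraph-class] objects.
#' @param enzyme enzyme label (normalized to the closed vocabulary).
#' @param declaredClass optional annotated reaction class.
#' @param trueAtom ground-truth reacting atom (synthetic records).
#' @return a [ReactionRecord-class].
#' @export
ReactionRecord <- function(substrate, product, enzyme = "other",
                           declaredClass = NA_character_,
                           trueAtom = NA_integer_) {
  new("ReactionRecord", substrate = substrate, product = product,
      enzyme = normalizeEnzyme(enzyme), declaredClass = declaredClass,
      assignedClass = NA_character_, mapping = NULL,
      trueAtom = as.integer(trueAtom), consistent = NA)
}

setMethod("show", "ReactionRecord", function(object) {
  cat(sprintf("ReactionRecord: %s -> %s [%s, %s]\n",
              object@substrate@name, object@product@name, object@enzyme,
              if (is.na(object@assignedClass)) object@declaredClass
              else object@assignedClass))
})

## ---------------------------------------------------------------------------
## TrainingSet
## ---------------------------------------------------------------------------

#' TrainingSet: per-class set of structures with one labelled atom
#'
#' `solas` has one row per SoLA: `mol` (index into `molecules`), `atom`
#' (heavy-atom index) and `positive`.
#'
#' @slot reactionClass the reaction class trained for.
#' @slot negativeType `"type1"` (any heavy atom) or `"type2"` (atoms of the
#'   class's characteristic element only).
#' @slot molecules list of `MolecularGraph` substrates.
#' @slot solas data.frame of SoLAs.
#' @slot provenance free-text description of the source.
#' @export
setClass("TrainingSet", representation(
  reactionClass = "character",
  negativeType  = "character",
  molecules     = "list",
  solas         = "data.frame",
  provenance    = "character"
))

setValidity("TrainingSet", function(object) {
  s <- object@solas
  if (!all(c("mol", "atom", "positive") %in% names(s)))
    return("solas must have columns mol, atom, positive")
  if (anyDuplicated(s[c("mol", "atom")]))
    return("duplicate (molecule, labelled atom) pairs")
  if (nrow(s) > 0 && (max(s$mol) > length(object@molecules) || min(s$mol) < 1))
    return("sola molecule index out of range")
  if (!object@negativeType %in% c("type1", "type2"))
    return("negativeType must be type1 or type2")
  TRUE
})

#' @describeIn TrainingSet-accessors SoLA table
#' @export
solas <- function(x) x@solas

#' Accessors for TrainingSet
#' @param x a `TrainingSet`.
#' @name TrainingSet-accessors
NULL

#' @describeIn TrainingSet-accessors list of substrate molecules
#' @export
trainingMolecules <- function(x) x@molecules

setMethod("show", "TrainingSet", function(object) {
  s <- object@solas
  cat(sprintf(
    "TrainingSet '%s' (%s): %d molecules, %d SoLAs (%d positive, %d negative)\n",
    object@reactionClass, object@negativeType, length(object@molecules),
    nrow(s), sum(s$positive), sum(!s$positive)))
})

## ---------------------------------------------------------------------------
## ClassModel
## ---------------------------------------------------------------------------

#' ClassModel: trained count tables and score distributions for one class
#'
#' Holds the frequency counts from which all probabilities derive: `N`
#' (total SoLAs), `Nk` (positive SoLAs) and, per descriptor, `Ni` (SoLAs
#' containing it) and `Nik` (positive SoLAs containing it). After
#' leave-one-out scoring, `posB`/`negB` hold the sorted LOO B values of the
#' positive/negative training examples, from which Pt and Pf are read at
#' prediction time.
#'
#' @slot reactionClass reaction class.
#' @slot negativeType negative-example scheme used.
#' @slot maxLevel,levelsMode,grammar descriptor configuration.
#' @slot N,Nk total and positive SoLA counts.
#' @slot descriptors,Ni,Nik parallel descriptor count tables.
#' @slot posB,negB sorted leave-one-out B values.
#' @export
setClass("ClassModel", representation(
  reactionClass = "character",
  negativeType  = "character",
  maxLevel      = "integer",
  levelsMode    = "character",
  grammar       = "character",
  N             = "integer",
  Nk            = "integer",
  descriptors   = "character",
  Ni            = "integer",
  Nik           = "integer",
  posB          = "numeric",
  negB          = "numeric"
))

setValidity("ClassModel", function(object) {
  if (object@Nk < 0 || object@Nk > object@N) return("need 0 <= Nk <= N")
  if (length(object@Ni) != length(object@descriptors) ||
      length(object@Nik) != length(object@descriptors))
    return("Ni/Nik must parallel descriptors")
  if (any(object@Nik > object@Ni)) return("Nik must not exceed Ni")
  if (any(object@Ni > object@N)) return("Ni must not exceed N")
  if (any(object@Nik > object@Nk)) return("Nik must not exceed Nk")
  TRUE
})

setMethod("show", "ClassModel", function(object) {
  cat(sprintf(
    "ClassModel '%s' (%s): N=%d, Nk=%d, %d descriptors (level <= %d, %s)%s\n",
    object@reactionClass, object@negativeType, object@N, object@Nk,
    length(object@descriptors), object@maxLevel, object@levelsMode,
    if (length(object@posB)) "" else " [no LOO distributions yet]"))
})

#' Prior probability P(Tk) of a trained model
#' @param model a `ClassModel`.
#' @return `Nk / N`.
#' @export
priorProbability <- function(model) model@Nk / model@N

#' Per-descriptor conditional probabilities P(Tk|Di)
#' @param model a `ClassModel`.
#' @return named numeric vector `Nik / Ni`.
#' @export
conditionalProbabilities <- function(model)
  setNames(model@Nik / model@Ni, model@descriptors)
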
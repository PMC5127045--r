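## Labelled Multilevel Neighbourhoods of Atoms (LMNA) descriptors.
##
## The level-0 descriptor of an atom is its atom type: an optional "*" mark
## when the atom is the labelled atom, then "-" when the atom is not in any
## ring, then the element symbol. The level-n descriptor is the atom type
## followed by the lexicographically sorted level-(n-1) descriptors of all
## neighbours (hydrogens included) in parentheses. The "*" mark propagates
## into neighbours' descriptors, so environments within `level` bonds of
## the label "feel" it. Sorting uses byte order (radix) so canonical
## strings are locale-independent.

.LMNA_GRAMMAR <- "lmna/1"

# character matrix [atom x (maxLevel+1)] of descriptors, no label
.lmnaBaseTable <- function(g, maxLevel, adj = .adjacency(g)) {
  t0 <- paste0(ifelse(g@atoms$ring, "", "-"), g@atoms$element)
  n <- length(t0)
  tab <- matrix("", nrow = n, ncol = maxLevel + 1L)
  tab[, 1L] <- t0
  for (l in seq_len(maxLevel)) {
    prev <- tab[, l]
    tab[, l + 1L] <- vapply(seq_len(n), function(a) paste0(
      t0[a], "(",
      paste0(sort(prev[adj[[a]]], method = "radix"), collapse = ""), ")"),
      character(1))
  }
  tab
}

# BFS distances from one atom over the full (hydrogen-included) graph
.bfsDist <- function(adj, from) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d[is.na(d)] <- .Machine$integer.max
  d
}

# label-aware table derived from the base table: only atoms within `l`
# bonds of the label need recomputation at level l
.lmnaLabelTable <- function(g, labelled, maxLevel, adj, base, dist) {
  tab <- base
  tab[labelled, 1L] <- paste0("*", base[labelled, 1L])
  for (l in seq_len(maxLevel)) {
    aff <- which(dist <= l)
    prev <- tab[, l]
    for (a in aff) tab[a, l + 1L] <- paste0(
      tab[a, 1L], "(",
      paste0(sort(prev[adj[[a]]], method = "radix"), collapse = ""), ")")
  }
  tab
}

#' Single MNA descriptor of one atom
#'
#' @param graph a [MolecularGraph-class].
#' @param atom atom index (hydrogens allowed).
#' @param level neighbourhood level (0 = atom type only).
#' @param labelled optional labelled-atom index (the "*" mark).
#' @return descriptor string.
#' @examples
#' \dontrun{
#' g <- parseMolecule("C", name = "methane")
#' mnaDescriptor(g, 1, 1, labelled = 1)  # "*-C(-H-H-H-H)"
#' }
#' @export
mnaDescriptor <- function(graph, atom, level, labelled = NA) {
  n <- nrow(graph@atoms)
  if (!is.numeric(atom) || length(atom) != 1L || atom < 1 || atom > n)
    stop("invalid atom index")
  adj <- .adjacency(graph)
  base <- .lmnaBaseTable(graph, level, adj)
  if (!is.na(labelled)) {
    dist <- .bfsDist(adj, as.integer(labelled))
    base <- .lmnaLabelTable(graph, as.integer(labelled), level, adj, base, dist)
  }
  base[atom, level + 1L]
}

#' LMNA descriptor set of a SoLA
#'
#' The set union of the descriptors of all atoms (heavy and hydrogen) of
#' the molecule with the labelled atom marked, over levels `1..maxLevel`
#' (`mode = "upto"`) or level `maxLevel` only (`mode = "exact"`).
#' Duplicates collapse; the result is canonical (independent of atom input
#' order).
#'
#' @param graph a [MolecularGraph-class].
#' @param labelledAtom index of the labelled heavy atom.
#' @param maxLevel maximum neighbourhood level (default 2).
#' @param mode `"upto"` or `"exact"`.
#' @return sorted character vector of descriptors; attribute `m` holds the
#'   set size.
#' @export
lmnaSet <- function(graph, labelledAtom, maxLevel = 2L,
                    mode = c("upto", "exact")) {
  mode <- match.arg(mode)
  sets <- solaDescriptorSets(graph, labelledAtom, maxLevel, mode)
  sets[[1L]]
}

#' LMNA descriptor sets for several labelled atoms of one molecule
#'
#' Computes the label-free descriptor table once and, per label, reworks
#' only the atoms within `maxLevel` bonds of the label, which makes bulk
#' SoLA description cheap.
#'
#' @inheritParams lmnaSet
#' @param labelledAtoms vector of labelled-atom indices.
#' @return named list of sorted descriptor character vectors (one per
#'   labelled atom); each carries attribute `m`.
#' @export
solaDescriptorSets <- function(graph, labelledAtoms, maxLevel = 2L,
                               mode = c("upto", "exact")) {
  mode <- match.arg(mode)
  maxLevel <- as.integer(maxLevel)
  if (maxLevel < 1L) stop("maxLevel must be >= 1")
  adj <- .adjacency(graph)
  base <- .lmnaBaseTable(graph, maxLevel, adj)
  cols <- if (mode == "upto") 2L:(maxLevel + 1L) else maxLevel + 1L
  out <- lapply(as.integer(labelledAtoms), function(t) {
    dist <- .bfsDist(adj, t)
    tab <- .lmnaLabelTable(graph, t, maxLevel, adj, base, dist)
    s <- sort(unique(as.vector(tab[, cols])), method = "radix")
    attr(s, "m") <- length(s)
    s
  })
  names(out) <- as.character(labelledAtoms)
  out
}

# descriptor sets for all rows of a TrainingSet's sola table, grouped by
# molecule; optional environment cache keyed by molecule name
.trainingDescriptorSets <- function(trainingSet, maxLevel = 2L,
                                    mode = "upto", cache = NULL) {
  s <- trainingSet@solas
  sets <- vector("list", nrow(s))
  for (k in unique(s$mol)) {
    rows <- which(s$mol == k)
    g <- trainingSet@molecules[[k]]
    key <- if (!is.null(cache))
      paste(g@name, nrow(g@atoms), maxLevel, mode, sep = "|") else NULL
    molSets <- if (!is.null(key) && !is.null(cache[[key]])) cache[[key]]
    else {
      ms <- solaDescriptorSets(g, heavyAtoms(g), maxLevel, mode)
      if (!is.null(key)) cache[[key]] <- ms
      ms
    }
    sets[rows] <- molSets[as.character(s$atom[rows])]
  }
  sets
}

#' Create a descriptor cache
#'
#' An environment reused across training, cross-validation and evaluation
#' so that the descriptor sets of a molecule are computed once.
#'
#' @return an environment.
#' @export
newDescriptorCache <- function() new.env(parent = emptyenv())

#' Dump SoLA descriptors as a TSV table
#'
#' @param trainingSet a [TrainingSet-class].
#' @param file output path, or `NULL` to return the data.frame.
#' @param maxLevel,mode descriptor configuration.
#' @return data.frame of (sola id, descriptor) pairs.
#' @export
writeDescriptorDump <- function(trainingSet, file = NULL, maxLevel = 2L,
                                mode = "upto") {
  sets <- .trainingDescriptorSets(trainingSet, maxLevel, mode)
  s <- trainingSet@solas
  ids <- sprintf("%s:%d", vapply(trainingSet@molecules[s$mol], slot, "", "name"),
                 s$atom)
  df <- data.frame(sola = rep(ids, lengths(sets)),
                   descriptor = unlist(sets), stringsAsFactors = FALSE)
  if (is.null(file)) return(df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
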
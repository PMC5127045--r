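## Structure I/O: SMILES / Molfile / SDF in, SDF out.
##
## All perception (aromaticity, implicit hydrogens) is delegated to
## OpenBabel through ChemmineOB; structures are converted to MOL2, whose
## atom-type column carries the aromaticity model, and read into a
## hydrogen-explicit MolecularGraph. Heavy atoms keep the input order;
## explicit hydrogens are appended.

.STD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, H = 1L)

# convert arbitrary input to multi-molecule MOL2 text, hydrogens added
.toMol2 <- function(text, from) {
  opts <- data.frame(names = "h", args = "")
  out <- tryCatch(
    ChemmineOB::convertFormat(from, "MOL2", source = text, options = opts),
    error = function(e) "")
  out
}

# parse one @<TRIPOS>MOLECULE block into a MolecularGraph (no policies yet)
.mol2Block <- function(block, name = NULL, source = "") {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  ai <- which(lines == "@<TRIPOS>ATOM")
  bi <- which(lines == "@<TRIPOS>BOND")
  if (length(ai) != 1L || length(bi) != 1L) return(NULL)
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  aEnd <- min(end[end > ai]) - 1L
  bEnd <- min(end[end > bi]) - 1L
  atomLines <- trimws(lines[(ai + 1L):aEnd])
  atomLines <- atomLines[nzchar(atomLines)]
  if (length(atomLines) == 0) return(NULL)
  af <- strsplit(atomLines, "\\s+")
  type <- vapply(af, `[`, "", 6L)
  element <- sub("\\..*$", "", type)
  atoms <- data.frame(
    element  = element,
    aromatic = grepl("\\.ar$", type),
    ring     = FALSE,
    charge   = 0L,
    hydrogen = element == "H",
    stringsAsFactors = FALSE)
  bondsDf <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (bi + 1L <= bEnd) {
    bondLines <- trimws(lines[(bi + 1L):bEnd])
    bondLines <- bondLines[nzchar(bondLines)]
    if (length(bondLines)) {
      bf <- strsplit(bondLines, "\\s+")
      ord <- vapply(bf, `[`, "", 4L)
      bondsDf <- data.frame(
        a1 = as.integer(vapply(bf, `[`, "", 2L)),
        a2 = as.integer(vapply(bf, `[`, "", 3L)),
        order = vapply(ord, function(o)
          switch(o, ar = 4L, am = 1L, du = 1L, un = 1L,
                 nc = 1L, as.integer(o)), integer(1), USE.NAMES = FALSE))
    }
  }
  if (is.null(name)) name <- trimws(lines[2L])
  g <- .newMolecularGraph(atoms, bondsDf, name = name, source = source)
  g@atoms$charge <- .inferFormalCharges(g)
  g
}

# MOL2 carries no formal charges; recover the common cases from valence.
.inferFormalCharges <- function(g) {
  adj <- .adjacency(g)
  ord <- integer(nrow(g@atoms))
  b <- g@bonds
  if (nrow(b)) {
    eff <- ifelse(b$order == 4L, 1L, b$order)   # aromatic counted once here
    for (i in seq_len(nrow(b))) {
      ord[b$a1[i]] <- ord[b$a1[i]] + eff[i]
      ord[b$a2[i]] <- ord[b$a2[i]] + eff[i]
    }
  }
  el <- g@atoms$element
  chg <- integer(length(el))
  chg[el == "N" & ord > 3L & !g@atoms$aromatic] <- 1L
  chg[el == "O" & ord == 1L & .hCounts(g, adj) == 0L &
        vapply(adj, function(nb) any(chg[nb] > 0L), logical(1))] <- -1L
  chg
}

.splitMol2 <- function(mol2) {
  parts <- strsplit(mol2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  lapply(parts, function(p) paste0("@<TRIPOS>MOLECULE", p))
}

# multi-component policy: keep the largest connected component, warn
.largestComponent <- function(g) {
  n <- nrow(g@atoms)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(g@bonds))
    ig <- igraph::add_edges(ig, rbind(g@bonds$a1, g@bonds$a2))
  comp <- igraph::components(ig)
  if (comp$no <= 1L) return(g)
  sizes <- vapply(seq_len(comp$no), function(k)
    sum(!g@atoms$hydrogen[comp$membership == k]), integer(1))
  keep <- which(comp$membership == which.max(sizes))
  warning(sprintf("'%s': %d components; keeping largest (%d heavy atoms)",
                  g@name, comp$no, max(sizes)), call. = FALSE)
  idx <- match(seq_len(n), keep)
  b <- g@bonds[g@bonds$a1 %in% keep & g@bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2]
  .newMolecularGraph(g@atoms[keep, , drop = FALSE], b,
                     name = g@name, source = g@source)
}

#' Parse a molecule into a hydrogen-explicit MolecularGraph
#'
#' Reads a single structure from a SMILES string or an MDL Molfile block,
#' perceives aromaticity and ring membership, and materializes all implicit
#' hydrogens as explicit atoms (appended after the heavy atoms, whose input
#' order is preserved). Multi-component inputs (salts, mixtures) are reduced
#' to their largest connected component with a warning.
#'
#' @param text structure string (one SMILES, or a complete Molfile/SDF
#'   record).
#' @param format `"smiles"` or `"molfile"`.
#' @param name optional molecule name (overrides any name in the input).
#' @return a [MolecularGraph-class] object.
#' @examples
#' \dontrun{
#' parseMolecule("CCO", name = "ethanol")
#' }
#' @export
parseMolecule <- function(text, format = c("smiles", "molfile"), name = NULL) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty structure input")
  if (format == "smiles") {
    smi <- trimws(text)
    if (grepl("[\t ]", smi)) {
      if (is.null(name)) name <- sub("^\\S+[\t ]+", "", smi)
      smi <- sub("[\t ].*$", "", smi)
    }
    mol2 <- .toMol2(paste0(smi, "\n"), "SMI")
    src <- smi
  } else {
    txt <- text
    if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$\n")
    mol2 <- .toMol2(txt, "SDF")
    src <- "molfile"
  }
  blocks <- .splitMol2(mol2)
  if (length(blocks) == 0)
    stop(sprintf("could not parse %s input '%s'", format,
                 substr(trimws(text), 1, 60)))
  g <- .mol2Block(blocks[[1L]], name = name, source = src)
  if (is.null(g)) stop("malformed structure block")
  .largestComponent(g)
}

#' Read a SMILES file (one molecule per line, optional tab-separated name)
#'
#' Lines that fail to parse are skipped with a warning and reported in the
#' `failures` attribute of the result.
#'
#' @param path file path.
#' @return list of [MolecularGraph-class] objects; attribute `failures` is a
#'   data.frame of skipped lines.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mols <- list()
  fail <- data.frame(line = integer(0), text = character(0))
  for (i in seq_along(lines)) {
    g <- tryCatch(suppressWarnings(parseMolecule(lines[i], "smiles")),
                  error = function(e) NULL)
    if (is.null(g)) {
      fail <- rbind(fail, data.frame(line = i, text = lines[i]))
      warning("skipping unparsable SMILES at line ", i, call. = FALSE)
    } else mols[[length(mols) + 1L]] <- g
  }
  attr(mols, "failures") <- fail
  mols
}

#' Read an SDF file into a list of MolecularGraphs
#'
#' @param path file path to an MDL SDF file (V2000).
#' @return list of [MolecularGraph-class] objects.
#' @export
readSDFFile <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  mol2 <- .toMol2(paste0(txt, "\n"), "SDF")
  blocks <- .splitMol2(mol2)
  if (length(blocks) == 0) stop("no parsable records in ", path)
  lapply(blocks, function(b) .largestComponent(.mol2Block(b, source = "sdf")))
}

## SDF writer -----------------------------------------------------------------

.sdfBlock <- function(g, fields = list()) {
  a <- g@atoms; b <- g@bonds
  out <- c(g@name, "  metaboRA", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  out <- c(out, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, a$element))
  if (nrow(b))
    out <- c(out, sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order))
  chg <- which(a$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0(sprintf("M  CHG%3d", length(grp)),
                           paste(sprintf("%4d%4d", grp, a$charge[grp]),
                                 collapse = "")))
    }
  }
  out <- c(out, "M  END")
  for (key in names(fields)) {
    out <- c(out, sprintf(">  <%s>", key),
             as.character(fields[[key]]), "")
  }
  c(out, "$$$$")
}

#' Write molecules as an MDL SDF file
#'
#' Optional per-molecule annotations are carried as SDF data fields; a
#' field value that is a named numeric/character vector with 1-based atom
#' numbers as names is rendered one entry per line. Prediction exports use
#' the fields `RA_CLASS` and `RA_RANKS` (one `atomNumber:rank:deltaP`
#' triple per line).
#'
#' @param molecules a `MolecularGraph` or list of them.
#' @param file output path, or `NULL` to return the SDF text.
#' @param annotations optional list (one element per molecule) of named
#'   lists of data fields; per-atom fields must be indexed by 1-based atom
#'   number.
#' @return the SDF text, invisibly when written to a file.
#' @export
writeSDF <- function(molecules, file = NULL, annotations = NULL) {
  if (is(molecules, "MolecularGraph")) molecules <- list(molecules)
  blocks <- character(0)
  for (i in seq_along(molecules)) {
    g <- molecules[[i]]
    fields <- if (is.null(annotations)) list() else annotations[[i]]
    fields <- lapply(fields, function(v) {
      if (!is.null(names(v))) {
        idx <- suppressWarnings(as.integer(names(v)))
        if (anyNA(idx) || any(idx < 1L | idx > nrow(g@atoms)))
          stop("annotation atom index out of range for '", g@name, "'")
        sprintf("%d:%s", idx, as.character(v))
      } else as.character(v)
    })
    blocks <- c(blocks, .sdfBlock(g, fields))
  }
  txt <- paste0(paste(blocks, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(blocks, file)
  invisible(txt)
}

#' Canonical SMILES of molecules
#'
#' Canonicalization is delegated to OpenBabel; used for deduplication of
#' identical structures and for tabular reaction output.
#'
#' @param molecules a `MolecularGraph` or list of them.
#' @return character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(molecules) {
  if (is(molecules, "MolecularGraph")) molecules <- list(molecules)
  sdf <- writeSDF(molecules)
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = sdf)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(molecules))
    stop("canonicalization failed for some molecules")
  vapply(strsplit(lines, "[\t ]"), `[`, "", 1L)
}

# isomorphism of full hydrogen-explicit graphs (element-coloured); used as
# the round-trip oracle and by tests
.graphsIsomorphic <- function(g1, g2) {
  if (nrow(g1@atoms) != nrow(g2@atoms)) return(FALSE)
  els <- sort(unique(c(g1@atoms$element, g2@atoms$element)))
  mk <- function(g) {
    ig <- igraph::make_empty_graph(n = nrow(g@atoms), directed = FALSE)
    if (nrow(g@bonds))
      ig <- igraph::add_edges(ig, rbind(g@bonds$a1, g@bonds$a2))
    ig
  }
  igraph::is_isomorphic_to(mk(g1), mk(g2), method = "vf2",
    vertex.color1 = match(g1@atoms$element, els),
    vertex.color2 = match(g2@atoms$element, els))
}
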
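## Reacting-atom identification by subgraph-isomorphism embedding.
##
## The heavy-atom skeleton of the smaller structure is embedded into the
## larger one (element-preserving monomorphism, bond orders ignored; VF2
## with element colours). Embeddings whose leftover fragment in the larger
## graph is disconnected are discarded; the reacting atoms are the embedded
## atoms whose heavy-neighbour count or hydrogen count changed, expressed
## as substrate indices and unioned over all surviving embeddings (so
## symmetry-equivalent sites are all reported).

#' Find all embeddings of one heavy-atom skeleton into another
#'
#' Every returned mapping is an injective, element-preserving,
#' adjacency-preserving embedding of the heavy-atom graph of `small` into
#' that of `large`; bond orders are ignored so that oxidation-state changes
#' do not break the embedding. The full deduplicated set is returned.
#'
#' @param small,large hydrogen-explicit [MolecularGraph-class] objects with
#'   `heavyAtomCount(small) <= heavyAtomCount(large)`.
#' @return list of integer vectors; element `i` of a mapping is the
#'   `large` atom index onto which heavy atom `i` (in `small`'s heavy-atom
#'   ordering, names give the `small` atom index) is mapped.
#' @export
findEmbeddings <- function(small, large) {
  if (heavyAtomCount(small) > heavyAtomCount(large))
    stop("heavy-atom count of 'small' exceeds 'large'; swap the arguments")
  gs <- .heavySkeleton(small)
  gl <- .heavySkeleton(large)
  els <- sort(unique(c(igraph::V(gs)$element, igraph::V(gl)$element)))
  maps <- igraph::subgraph_isomorphisms(
    pattern = gs, target = gl, method = "vf2",
    vertex.color1 = match(igraph::V(gl)$element, els),
    vertex.color2 = match(igraph::V(gs)$element, els))
  out <- lapply(maps, function(m)
    stats::setNames(igraph::V(gl)$orig[as.integer(m)], igraph::V(gs)$orig))
  out[!duplicated(vapply(out, paste, "", collapse = ","))]
}

# connectedness of the induced subgraph of `skel` on vertex set `vs`
.connectedSubset <- function(skel, vs) {
  if (length(vs) <= 1L) return(TRUE)
  sub <- igraph::induced_subgraph(skel, vs)
  igraph::components(sub)$no == 1L
}

#' Identify the reacting atom(s) of a substrate/product pair
#'
#' Determines the reaction direction from the heavy-atom counts, embeds the
#' smaller skeleton into the larger, discards embeddings whose graph
#' difference is disconnected, and reports every embedded atom whose
#' neighbourhood (heavy-neighbour count or hydrogen count) changed. When
#' substrate and product have equal heavy-atom counts (e.g. an alcohol to
#' carbonyl C-oxidation) the embeddings are the skeleton isomorphisms and
#' only hydrogen counts can differ.
#'
#' @param substrate,product [MolecularGraph-class] objects.
#' @param classHint optional reaction class; reacting atoms are then
#'   filtered to the class's characteristic element.
#' @return a [ReactionMapping-class]; reacting atoms are substrate indices.
#' @export
identifyReactingAtoms <- function(substrate, product, classHint = NULL) {
  elFilter <- if (!is.null(classHint)) classElement(classHint) else NA
  ns <- heavyAtomCount(substrate)
  np <- heavyAtomCount(product)

  adjS <- .adjacency(substrate); adjP <- .adjacency(product)
  hS <- .hCounts(substrate, adjS); hP <- .hCounts(product, adjP)
  dS <- .heavyDegree(substrate, adjS); dP <- .heavyDegree(product, adjP)

  if (ns == np) {
    maps <- findEmbeddings(substrate, product)
    if (length(maps) == 0)
      stop("not a single-fragment transformation: no embedding found")
    ra <- integer(0)
    for (m in maps) {
      sm <- as.integer(names(m))
      ra <- union(ra, sm[hS[sm] != hP[m]])   # degrees preserved by isomorphism
    }
    if (length(ra) == 0) stop("no structural change between substrate and product")
    if (!is.na(elFilter))
      ra <- ra[substrate@atoms$element[ra] == elFilter]
    return(new("ReactionMapping", direction = "none",
               embedding = maps[[1L]], reactingAtoms = sort(ra),
               changedFragment = integer(0), fragmentConnected = TRUE,
               nEmbeddings = length(maps)))
  }

  addition <- np > ns
  small <- if (addition) substrate else product
  large <- if (addition) product else substrate
  hSm <- if (addition) hS else hP; hLg <- if (addition) hP else hS
  dSm <- if (addition) dS else dP; dLg <- if (addition) dP else dS

  maps <- findEmbeddings(small, large)
  if (length(maps) == 0)
    stop("not a single-fragment transformation: no embedding found")

  skelL <- .heavySkeleton(large)
  largeHeavy <- igraph::V(skelL)$orig
  surviving <- list(); frag <- integer(0)
  ra <- integer(0)
  for (m in maps) {
    fr <- setdiff(largeHeavy, m)
    if (!.connectedSubset(skelL, match(fr, largeHeavy))) next
    surviving[[length(surviving) + 1L]] <- m
    if (length(surviving) == 1L) frag <- sort(fr)
    sm <- as.integer(names(m))
    changed <- sm[dSm[sm] != dLg[m] | hSm[sm] != hLg[m]]
    # express as substrate indices
    ra <- union(ra, if (addition) changed else unname(m[match(changed, sm)]))
  }
  if (length(surviving) == 0) {
    warning("multi-site reaction: graph difference disconnected for every embedding",
            call. = FALSE)
    return(new("ReactionMapping",
               direction = if (addition) "addition" else "removal",
               embedding = maps[[1L]], reactingAtoms = integer(0),
               changedFragment = integer(0), fragmentConnected = FALSE,
               nEmbeddings = 0L))
  }
  if (!is.na(elFilter))
    ra <- ra[substrate@atoms$element[ra] == elFilter]
  new("ReactionMapping",
      direction = if (addition) "addition" else "removal",
      embedding = surviving[[1L]], reactingAtoms = sort(as.integer(ra)),
      changedFragment = frag, fragmentConnected = TRUE,
      nEmbeddings = length(surviving))
}

## ---------------------------------------------------------------------------
## Reaction-class assignment
## ---------------------------------------------------------------------------

# glucuronyl moiety: six-membered O-heterocycle (1 O + 5 C) bearing a
# carboxyl carbon and at least three hydroxyls, 12 heavy atoms in all
.isGlucuronylFragment <- function(g, fragIdx) {
  el <- g@atoms$element[fragIdx]
  if (length(fragIdx) != 12L || sum(el == "C") != 6L || sum(el == "O") != 6L)
    return(FALSE)
  adj <- .adjacency(g)
  hC <- .hCounts(g, adj)
  inFrag <- function(v) v[v %in% fragIdx]
  ringAtoms <- fragIdx[g@atoms$ring[fragIdx]]
  if (sum(g@atoms$element[ringAtoms] == "O") < 1L) return(FALSE)
  carboxylC <- any(vapply(fragIdx[el == "C"], function(c) {
    os <- inFrag(adj[[c]]); os <- os[g@atoms$element[os] == "O"]
    sum(!g@atoms$ring[os]) >= 2L
  }, logical(1)))
  hydroxyls <- sum(g@atoms$element[fragIdx] == "O" & hC[fragIdx] == 1L)
  carboxylC && hydroxyls >= 3L
}

#' Assign the biotransformation class of a mapped reaction
#'
#' Applies the rule table over the mapping's direction, the changed
#' fragment, and the local environment of the reacting atom: single O added
#' at an aromatic/aliphatic C is aromatic/aliphatic hydroxylation (or
#' C-oxidation when the added O is a carbonyl), O at N/S is N-/S-oxidation,
#' a carboxyl or a hydrogen-loss C=O formation is C-oxidation, a glucuronyl
#' fragment at N/O is N-/O-glucuronidation, and removal of a carbon-only
#' fragment from N/O is N-/O-dealkylation. A UGT enzyme tag is only
#' consistent with the glucuronidation classes, a CYP tag with the other
#' seven; contradictions are flagged with a warning and an
#' `inconsistent` attribute.
#'
#' @param mapping a [ReactionMapping-class] from [identifyReactingAtoms()].
#' @param substrate,product the structures the mapping was computed from.
#' @param enzyme enzyme family label (normalized via [normalizeEnzyme()]).
#' @return reaction class name (character scalar).
#' @export
assignReactionClass <- function(mapping, substrate, product, enzyme = "other") {
  enzyme <- normalizeEnzyme(enzyme)
  ra <- mapping@reactingAtoms
  if (length(ra) == 0) stop("no reacting atoms; cannot classify")
  el <- unique(substrate@atoms$element[ra])
  if (length(el) != 1L)
    stop("ambiguous reaction: reacting atoms of several elements (",
         paste(el, collapse = ","), "); supply a class hint")
  r <- ra[1L]
  adjS <- .adjacency(substrate); adjP <- .adjacency(product)
  hP <- .hCounts(product, adjP); hS <- .hCounts(substrate, adjS)
  frag <- mapping@changedFragment

  cls <- NULL
  if (mapping@direction == "addition") {
    fel <- product@atoms$element[frag]
    rImg <- unname(mapping@embedding[match(r, as.integer(names(mapping@embedding)))])
    if (length(frag) == 1L && fel == "O") {
      if (el == "N") cls <- "N_oxidation"
      else if (el == "S") cls <- "S_oxidation"
      else if (el == "C") {
        carbonyl <- hP[frag] == 0L
        cls <- if (carbonyl) "C_oxidation"
               else if (substrate@atoms$aromatic[r]) "aromatic_hydroxylation"
               else "aliphatic_hydroxylation"
      }
    } else if (el == "C" && length(frag) == 3L &&
               sum(fel == "O") == 2L && sum(fel == "C") == 1L) {
      cls <- "C_oxidation"   # carboxyl formation
    } else if (.isGlucuronylFragment(product, frag)) {
      if (el == "N") cls <- "N_glucuronidation"
      else if (el == "O") cls <- "O_glucuronidation"
    }
  } else if (mapping@direction == "removal") {
    fel <- substrate@atoms$element[frag]
    if (all(fel == "C")) {
      if (el == "N") cls <- "N_dealkylation"
      else if (el == "O") cls <- "O_dealkylation"
    }
  } else {
    # equal heavy counts: C=O formation at a carbon that lost hydrogen(s)
    if (el == "C") {
      oNb <- adjS[[r]]
      oNb <- oNb[substrate@atoms$element[oNb] == "O"]
      if (length(oNb) > 0L) cls <- "C_oxidation"
    }
  }
  if (is.null(cls))
    stop(structure(class = c("ra_unclassified", "error", "condition"),
                   list(message = "unclassified reaction", call = sys.call())))
  inconsistent <-
    (enzyme == "UGT" && !cls %in% .GLUC_CLASSES) ||
    (enzyme %in% .CYP_FAMILIES && cls %in% .GLUC_CLASSES)
  if (inconsistent) {
    warning(sprintf("enzyme %s contradicts assigned class %s", enzyme, cls),
            call. = FALSE)
    attr(cls, "inconsistent") <- TRUE
  }
  cls
}

#' Map a reaction record: identify reacting atoms and assign its class
#'
#' Fills the `mapping` and `assignedClass` slots; when a declared class is
#' present it is used as the element hint and checked for consistency.
#'
#' @param record a [ReactionRecord-class].
#' @return the updated record; `consistent` is `FALSE` when the declared
#'   and assigned classes disagree.
#' @export
mapReactionRecord <- function(record) {
  hint <- if (!is.na(record@declaredClass)) record@declaredClass else NULL
  m <- identifyReactingAtoms(record@substrate, record@product, classHint = hint)
  record@mapping <- m
  cls <- tryCatch(
    assignReactionClass(m, record@substrate, record@product, record@enzyme),
    ra_unclassified = function(e) NA_character_)
  record@assignedClass <- as.character(cls)
  record@consistent <- if (is.na(record@declaredClass) || is.na(record@assignedClass))
    NA else identical(as.character(cls), record@declaredClass)
  record
}

## ---------------------------------------------------------------------------
## Tabular reaction I/O
## ---------------------------------------------------------------------------

#' Read a reaction table (TSV/CSV of substrate/product SMILES pairs)
#'
#' Required columns: `substrate_smiles`, `product_smiles`; optional:
#' `name`, `enzyme`, `class`. Rows whose structures fail to parse are
#' skipped and reported, not fatal.
#'
#' @param path file path; tab- or comma-separated with a header.
#' @return list with `records` (list of [ReactionRecord-class]) and
#'   `failures` (data.frame of row numbers and reasons).
#' @export
readReactionTable <- function(path) {
  if (!file.exists(path)) stop("cannot read reaction table: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("substrate_smiles", "product_smiles")
  if (!all(need %in% names(df)))
    stop("reaction table must have columns substrate_smiles, product_smiles")
  if (nrow(df) == 0) stop("no records in ", path)
  records <- list()
  failures <- data.frame(row = integer(0), reason = character(0))
  for (i in seq_len(nrow(df))) {
    nm <- if ("name" %in% names(df)) df$name[i] else sprintf("rxn_%03d", i)
    rec <- tryCatch({
      s <- suppressWarnings(parseMolecule(df$substrate_smiles[i], "smiles",
                                          name = nm))
      p <- suppressWarnings(parseMolecule(df$product_smiles[i], "smiles",
                                          name = paste0(nm, "_prod")))
      ReactionRecord(s, p,
        enzyme = if ("enzyme" %in% names(df)) df$enzyme[i] else "other",
        declaredClass = if ("class" %in% names(df) && nzchar(df$class[i]))
          df$class[i] else NA_character_)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      failures <- rbind(failures, data.frame(row = i, reason = rec))
    } else records[[length(records) + 1L]] <- rec
  }
  list(records = records, failures = failures)
}

#' Write a mapping report for a set of reaction records
#'
#' One row per mapped record: substrate name, direction, reacting atom
#' numbers (1-based, `;`-separated) and assigned class.
#'
#' @param records list of mapped [ReactionRecord-class] objects.
#' @param file output TSV path, or `NULL` to return the data.frame.
#' @return the report data.frame, invisibly when written.
#' @export
writeMappingReport <- function(records, file = NULL) {
  df <- do.call(rbind, lapply(records, function(r) data.frame(
    substrate = r@substrate@name,
    direction = if (is.null(r@mapping)) NA_character_ else r@mapping@direction,
    reacting_atoms = if (is.null(r@mapping)) ""
      else paste(r@mapping@reactingAtoms, collapse = ";"),
    class = r@assignedClass,
    consistent = r@consistent,
    stringsAsFactors = FALSE)))
  if (is.null(file)) return(df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
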
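## Synthetic reaction benchmark.
##
## The real training data behind this method (a commercial metabolite
## database) cannot be shipped, so the generator emulates its statistical
## structure: seeded drug-like molecules are assembled from scaffolds and
## functional-group substituents, and rule-based transformations (one per
## elementary reaction class) are applied at pattern-matched sites, giving
## reaction records with atom-resolved ground truth. Substituent patterns
## are designed so that within one molecule a rule's matches are mutually
## symmetry-equivalent, which keeps the ground truth well-defined under
## the union-over-embeddings convention of the mapping step.

.STD_VALENCE_NUM <- c(C = 4, N = 3, O = 2, S = 2)

# heavy-fragment specs: element/aromatic/charge vectors, internal bonds
# (a1, a2, order), attachment atom index
.FRAGMENTS <- list(
  methyl        = list(el = "C", ar = FALSE, ch = 0L, bonds = NULL, at = 1L),
  ethyl         = list(el = c("C", "C"), ar = c(FALSE, FALSE), ch = c(0L, 0L),
                       bonds = rbind(c(1, 2, 1)), at = 1L),
  hydroxyl      = list(el = "O", ar = FALSE, ch = 0L, bonds = NULL, at = 1L),
  methoxy       = list(el = c("O", "C"), ar = c(FALSE, FALSE), ch = c(0L, 0L),
                       bonds = rbind(c(1, 2, 1)), at = 1L),
  methylthio    = list(el = c("S", "C"), ar = c(FALSE, FALSE), ch = c(0L, 0L),
                       bonds = rbind(c(1, 2, 1)), at = 1L),
  dimethylamino = list(el = c("N", "C", "C"), ar = rep(FALSE, 3),
                       ch = rep(0L, 3),
                       bonds = rbind(c(1, 2, 1), c(1, 3, 1)), at = 1L),
  methylamino   = list(el = c("N", "C"), ar = c(FALSE, FALSE), ch = c(0L, 0L),
                       bonds = rbind(c(1, 2, 1)), at = 1L),
  tertbutyl     = list(el = rep("C", 4), ar = rep(FALSE, 4), ch = rep(0L, 4),
                       bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)),
                       at = 1L),
  phenyl        = list(el = rep("C", 6), ar = rep(TRUE, 6), ch = rep(0L, 6),
                       bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1),
                                     c(4, 5, 2), c(5, 6, 1), c(6, 1, 2)),
                       at = 1L),
  glucuronyl    = list(
    # pyranose ring O1-C2-C3-C4-C5-C6, anomeric C2 is the attachment,
    # hydroxyls on C3..C5, carboxyl (C7, =O8, -O9) on C6
    el = c("O", "C", "C", "C", "C", "C", "O", "O", "O", "C", "O", "O"),
    ar = rep(FALSE, 12), ch = rep(0L, 12),
    bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1),
                  c(5, 6, 1), c(6, 1, 1),
                  c(3, 7, 1), c(4, 8, 1), c(5, 9, 1),
                  c(6, 10, 1), c(10, 11, 2), c(10, 12, 1)),
    at = 2L)
)

# append a heavy fragment at `at`, then hydrogen-fill the new atoms
.attachHeavyFragment <- function(g, at, frag, order = 1L) {
  n0 <- nrow(g@atoms)
  nf <- length(frag$el)
  atoms <- rbind(g@atoms,
                 data.frame(element = frag$el, aromatic = frag$ar,
                            ring = FALSE, charge = as.integer(frag$ch),
                            hydrogen = FALSE, stringsAsFactors = FALSE))
  bonds <- g@bonds
  if (!is.null(frag$bonds))
    bonds <- rbind(bonds, data.frame(a1 = frag$bonds[, 1] + n0,
                                     a2 = frag$bonds[, 2] + n0,
                                     order = as.integer(frag$bonds[, 3])))
  bonds <- rbind(bonds, data.frame(a1 = at, a2 = frag$at + n0,
                                   order = as.integer(order)))
  newIdx <- n0 + seq_len(nf)
  # hydrogen fill for the appended heavy atoms
  ordSum <- vapply(newIdx, function(a)
    sum(bonds$order[bonds$a1 == a | bonds$a2 == a]), numeric(1))
  hNeed <- pmax(0, .STD_VALENCE_NUM[atoms$element[newIdx]] +
                  atoms$charge[newIdx] - ordSum)
  for (j in seq_along(newIdx)) {
    if (hNeed[j] > 0) for (q in seq_len(hNeed[j])) {
      atoms <- rbind(atoms, data.frame(element = "H", aromatic = FALSE,
                                       ring = FALSE, charge = 0L,
                                       hydrogen = TRUE))
      bonds <- rbind(bonds, data.frame(a1 = newIdx[j],
                                       a2 = nrow(atoms), order = 1L))
    }
  }
  .newMolecularGraph(atoms, bonds, name = g@name, source = g@source)
}

.removeAtomsFromGraph <- function(g, idx) {
  keep <- setdiff(seq_len(nrow(g@atoms)), idx)
  map <- match(seq_len(nrow(g@atoms)), keep)
  b <- g@bonds[!(g@bonds$a1 %in% idx | g@bonds$a2 %in% idx), , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  .newMolecularGraph(g@atoms[keep, , drop = FALSE], b,
                     name = g@name, source = g@source)
}

# remove one explicit hydrogen attached to `at` (the highest-index one,
# so heavy-atom indices are never disturbed)
.removeOneH <- function(g, at) {
  adj <- .adjacency(g)
  hs <- adj[[at]][g@atoms$hydrogen[adj[[at]]]]
  if (length(hs) == 0L) stop("no hydrogen to remove at atom ", at)
  .removeAtomsFromGraph(g, max(hs))
}

.setBondOrder <- function(g, a, b, order) {
  i <- which((g@bonds$a1 == a & g@bonds$a2 == b) |
             (g@bonds$a1 == b & g@bonds$a2 == a))
  if (length(i) != 1L) stop("no unique bond between ", a, " and ", b)
  g@bonds$order[i] <- as.integer(order)
  g
}

.setCharge <- function(g, at, charge) {
  g@atoms$charge[at] <- as.integer(charge)
  g
}

## rule table -----------------------------------------------------------------

.methylNeighbours <- function(g, at, adj, hC, hd) {
  nb <- adj[[at]]
  nb <- nb[!g@atoms$hydrogen[nb]]
  nb[g@atoms$element[nb] == "C" & hC[nb] == 3L & hd[nb] == 1L]
}

.ruleEnv <- function(g) {
  adj <- .adjacency(g)
  list(adj = adj, hC = .hCounts(g, adj), hd = .heavyDegree(g, adj),
       el = g@atoms$element, ar = g@atoms$aromatic, ch = g@atoms$charge,
       hv = !g@atoms$hydrogen)
}

#' Rule-based transformations for the synthetic benchmark
#'
#' One [TransformationRule] per elementary reaction class; each is a
#' substructure matcher (`match(g)` returning candidate reacting atoms)
#' plus a graph edit (`edit(g, atom)` returning the product). Patterns
#' select sites whose matches within a molecule are symmetry-equivalent
#' and whose level-2 LMNA environment identifies them, so trained models
#' can recover them on held-out molecules.
#'
#' @return named list of rules.
#' @export
transformationRules <- function() {
  hydroxylEdit <- function(g, at) {
    g <- .removeOneH(g, at)
    .attachHeavyFragment(g, at, .FRAGMENTS$hydroxyl)
  }
  glucEdit <- function(g, at) {
    g <- .removeOneH(g, at)
    .attachHeavyFragment(g, at, .FRAGMENTS$glucuronyl)
  }
  mk <- function(name, class, enzymes, match, edit)
    structure(list(name = name, reactionClass = class, enzymes = enzymes,
                   match = match, edit = edit),
              class = "TransformationRule")
  list(
    aromatic_hydroxylation = mk("aromatic_hydroxylation",
      "aromatic_hydroxylation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "C" & e$ar & e$hC >= 1L & vapply(seq_along(e$adj),
          function(a) any(e$ar[e$adj[[a]]] & e$hd[e$adj[[a]]] == 3L &
                          !g@atoms$hydrogen[e$adj[[a]]]), logical(1)))
      },
      edit = hydroxylEdit),
    aliphatic_hydroxylation = mk("aliphatic_hydroxylation",
      "aliphatic_hydroxylation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        quat <- e$el == "C" & e$hd == 4L & vapply(seq_along(e$adj),
          function(a) all(e$el[e$adj[[a]]] == "C"), logical(1))
        which(e$el == "C" & e$hC == 3L & vapply(seq_along(e$adj),
          function(a) any(quat[e$adj[[a]]]), logical(1)))
      },
      edit = hydroxylEdit),
    N_oxidation = mk("N_oxidation", "N_oxidation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "N" & e$hd == 3L & e$hC == 0L & e$ch == 0L & !e$ar)
      },
      edit = function(g, at) {
        g <- .attachHeavyFragment(g, at, within(.FRAGMENTS$hydroxyl,
                                                ch <- -1L))
        .setCharge(g, at, 1L)
      }),
    S_oxidation = mk("S_oxidation", "S_oxidation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "S" & e$hd == 2L & vapply(seq_along(e$adj),
          function(a) !any(e$el[e$adj[[a]]] == "O"), logical(1)))
      },
      edit = function(g, at)
        .attachHeavyFragment(g, at, .FRAGMENTS$hydroxyl, order = 2L)),
    C_oxidation = mk("C_oxidation", "C_oxidation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        hydroxylO <- e$el == "O" & e$hd == 1L & e$hC == 1L
        which(e$el == "C" & e$hC >= 1L & vapply(seq_along(e$adj),
          function(a) any(hydroxylO[e$adj[[a]]]), logical(1)))
      },
      edit = function(g, at) {
        e <- .ruleEnv(g)
        o <- e$adj[[at]][e$el[e$adj[[at]]] == "O" &
                         e$hd[e$adj[[at]]] == 1L & e$hC[e$adj[[at]]] == 1L][1L]
        g <- .removeOneH(g, o)
        g <- .removeOneH(g, at)
        .setBondOrder(g, at, o, 2L)
      }),
    N_dealkylation = mk("N_dealkylation", "N_dealkylation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "N" & vapply(seq_along(e$adj), function(a)
          length(.methylNeighbours(g, a, e$adj, e$hC, e$hd)) > 0L, logical(1)))
      },
      edit = function(g, at) .demethylate(g, at)),
    O_dealkylation = mk("O_dealkylation", "O_dealkylation", .CYP_FAMILIES,
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "O" & e$hd == 2L & vapply(seq_along(e$adj), function(a)
          length(.methylNeighbours(g, a, e$adj, e$hC, e$hd)) > 0L, logical(1)))
      },
      edit = function(g, at) .demethylate(g, at)),
    N_glucuronidation = mk("N_glucuronidation", "N_glucuronidation", "UGT",
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "N" & e$hC >= 1L & e$ch == 0L)
      },
      edit = glucEdit),
    O_glucuronidation = mk("O_glucuronidation", "O_glucuronidation", "UGT",
      match = function(g) {
        e <- .ruleEnv(g)
        which(e$el == "O" & e$hd == 1L & e$hC == 1L)
      },
      edit = glucEdit)
  )
}

# remove one methyl from heteroatom `at` and restore a hydrogen there
.demethylate <- function(g, at) {
  e <- .ruleEnv(g)
  me <- min(.methylNeighbours(g, at, e$adj, e$hC, e$hd))
  hs <- e$adj[[me]][g@atoms$hydrogen[e$adj[[me]]]]
  removed <- c(me, hs)
  at2 <- at - sum(removed < at)
  g <- .removeAtomsFromGraph(g, removed)
  atoms <- rbind(g@atoms, data.frame(element = "H", aromatic = FALSE,
                                     ring = FALSE, charge = 0L,
                                     hydrogen = TRUE))
  bonds <- rbind(g@bonds, data.frame(a1 = at2, a2 = nrow(atoms), order = 1L))
  .newMolecularGraph(atoms, bonds, name = g@name, source = g@source)
}

## molecule generator ---------------------------------------------------------

.SUBSTITUENT_POOL <- c("phenyl", "tertbutyl", "methyl", "ethyl", "hydroxyl",
                       "methoxy", "methylthio", "dimethylamino", "methylamino")
.CARBON_SUBSTITUENTS <- c("phenyl", "tertbutyl", "methyl", "ethyl")
.AMINO_SUBSTITUENTS <- c("dimethylamino", "methylamino")

# sample() without the scalar-expansion surprise on length-1 vectors
.sampleOne <- function(x) x[sample.int(length(x), 1L)]
.sampleK <- function(x, k) x[sample.int(length(x), k)]

.generateOne <- function(i, params) {
  scaffold <- .sampleOne(params$scaffolds)
  if (scaffold == "chain") {
    len <- .sampleOne(seq(params$chainRange[1], params$chainRange[2]))
    atoms <- data.frame(element = rep("C", len), aromatic = FALSE,
                        ring = FALSE, charge = 0L, hydrogen = FALSE)
    bonds <- if (len > 1L)
      data.frame(a1 = seq_len(len - 1L), a2 = 2:len, order = 1L)
    else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    len <- 6L
    atoms <- data.frame(element = rep("C", 6L), aromatic = FALSE,
                        ring = TRUE, charge = 0L, hydrogen = FALSE)
    bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 1L)
  }
  g <- .newMolecularGraph(atoms, bonds, name = sprintf("synmol_%04d", i),
                          source = "synthetic")
  pool <- params$substituents
  nSub <- .sampleOne(seq(params$nSubstituents[1],
                         min(params$nSubstituents[2], len)))
  chosen <- .sampleK(pool, min(nSub, length(pool)))
  # at most one amino substituent: their methyl/NH patterns must stay unique
  amino <- chosen %in% .AMINO_SUBSTITUENTS
  if (sum(amino) > 1L) chosen <- chosen[!amino | cumsum(amino) == 1L]
  positions <- .sampleK(seq_len(len), length(chosen))
  for (j in seq_along(chosen))
    g <- .attachHeavyFragment(g, positions[j], .FRAGMENTS[[chosen[j]]])
  # hydrogen-fill the scaffold atoms now that substitution is final
  adj <- .adjacency(g)
  ordSum <- vapply(seq_len(len), function(a)
    sum(g@bonds$order[g@bonds$a1 == a | g@bonds$a2 == a]), numeric(1))
  atoms <- g@atoms; bonds <- g@bonds
  for (a in seq_len(len)) {
    need <- 4 - ordSum[a]
    if (need > 0) for (q in seq_len(need)) {
      atoms <- rbind(atoms, data.frame(element = "H", aromatic = FALSE,
                                       ring = FALSE, charge = 0L,
                                       hydrogen = TRUE))
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = nrow(atoms), order = 1L))
    }
  }
  .newMolecularGraph(atoms, bonds, name = g@name, source = "synthetic")
}

.defaultGenParams <- function(params = list()) {
  p <- list(scaffolds = c("chain", "ring"), chainRange = c(4L, 6L),
            nSubstituents = c(2L, 4L), substituents = .SUBSTITUENT_POOL,
            heteroatoms = TRUE)
  p[names(params)] <- params
  if (!isTRUE(p$heteroatoms))
    p$substituents <- intersect(p$substituents, .CARBON_SUBSTITUENTS)
  unknown <- setdiff(p$substituents, .SUBSTITUENT_POOL)
  if (length(unknown))
    stop("unsatisfiable generator parameters: unknown substituent ",
         paste(unknown, collapse = ", "))
  if (length(p$substituents) == 0L)
    stop("unsatisfiable generator parameters: empty substituent pool")
  if (p$nSubstituents[1] > p$nSubstituents[2] ||
      p$chainRange[1] > p$chainRange[2] || p$chainRange[1] < 3L)
    stop("unsatisfiable generator parameters: bad size ranges")
  p
}

#' Generate seeded drug-like synthetic molecules
#'
#' Molecules are assembled from a carbon scaffold (chain of 4-6 atoms or a
#' cyclohexane ring) carrying 2-4 distinct functional-group substituents
#' drawn from a fixed pool (phenyl, tert-butyl, methyl, ethyl, hydroxyl,
#' methoxy, methylthio, dimethylamino, methylamino), hydrogen-filled to
#' standard valences. 6-30 heavy atoms; deterministic given the seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param params optional overrides: `scaffolds`, `chainRange`,
#'   `nSubstituents`, `substituents`, `heteroatoms` (set `FALSE` for
#'   all-carbon skeletons).
#' @return list of [MolecularGraph-class] objects.
#' @export
generateMolecules <- function(n, seed = 1L, params = list()) {
  stopifnot(n >= 1)
  p <- .defaultGenParams(params)
  .withSeed(seed, lapply(seq_len(n), .generateOne, params = p))
}

#' Apply a transformation rule at a (seeded) matched site
#'
#' @param molecule a [MolecularGraph-class].
#' @param rule a rule from [transformationRules()].
#' @param site optional explicit site; must match the rule's pattern.
#' @param seed optional seed for the site choice (otherwise the current
#'   RNG stream is used).
#' @return a [ReactionRecord-class] whose `trueAtom` is the edited site
#'   and `declaredClass` the rule's class.
#' @export
applyRule <- function(molecule, rule, site = NULL, seed = NULL) {
  matches <- rule$match(molecule)
  if (length(matches) == 0L)
    stop("rule not applicable: no match for ", rule$name,
         " in ", molecule@name)
  if (is.null(site)) {
    site <- .withSeed(seed, matches[sample.int(length(matches), 1L)])
  } else if (!site %in% matches)
    stop("site ", site, " does not match rule ", rule$name)
  product <- rule$edit(molecule, site)
  product@name <- paste0(molecule@name, "_", rule$name)
  enzyme <- if (length(rule$enzymes) == 1L) rule$enzymes
            else .withSeed(NULL, sample(rule$enzymes, 1L))
  ReactionRecord(molecule, product, enzyme = enzyme,
                 declaredClass = rule$reactionClass, trueAtom = site)
}

#' Build a synthetic reaction benchmark with known reacting atoms
#'
#' Generates `nMolecules` seeded molecules and applies every applicable
#' rule to each, recording the chosen site as ground truth. Every record
#' reproduces its stored atom through [identifyReactingAtoms()] (the
#' round-trip property tested in the suite).
#'
#' @param nMolecules number of molecules (default 200).
#' @param seed integer seed (default 42).
#' @param rules rules to apply (default [transformationRules()]).
#' @param params generator parameter overrides, see [generateMolecules()].
#' @return object of class `SyntheticBenchmark`: list with `records`,
#'   `molecules`, `rules`, `seed`, `nMolecules`.
#' @export
makeBenchmark <- function(nMolecules = 200L, seed = 42L,
                          rules = transformationRules(), params = list()) {
  if (length(rules) == 0L) stop("need at least one rule")
  p <- .defaultGenParams(params)
  out <- .withSeed(seed, {
    mols <- lapply(seq_len(nMolecules), .generateOne, params = p)
    records <- list()
    for (m in mols) for (rule in rules) {
      if (length(rule$match(m)) == 0L) next
      records[[length(records) + 1L]] <- applyRule(m, rule)
    }
    list(molecules = mols, records = records)
  })
  if (length(out$records) == 0L) stop("no applicable records generated")
  structure(list(records = out$records, molecules = out$molecules,
                 rules = names(rules), seed = seed,
                 nMolecules = nMolecules),
            class = "SyntheticBenchmark")
}

#' @export
print.SyntheticBenchmark <- function(x, ...) {
  cls <- table(vapply(x$records, slot, "", "declaredClass"))
  cat(sprintf("SyntheticBenchmark: %d molecules, %d records (seed %d)\n",
              x$nMolecules, length(x$records), x$seed))
  for (k in names(cls)) cat(sprintf("  %-24s %d\n", k, cls[[k]]))
  invisible(x)
}

#' Write benchmark records as a reaction table (TSV)
#'
#' Columns: name, substrate_smiles, product_smiles, enzyme, class,
#' true_atom. Deterministic for a given benchmark.
#'
#' @param records a `SyntheticBenchmark` or list of
#'   [ReactionRecord-class] objects.
#' @param file output path, or `NULL` to return the data.frame.
#' @return the data.frame, invisibly when written.
#' @export
writeReactionTable <- function(records, file = NULL) {
  if (inherits(records, "SyntheticBenchmark")) records <- records$records
  subs <- canonicalSmiles(lapply(records, slot, "substrate"))
  prods <- canonicalSmiles(lapply(records, slot, "product"))
  df <- data.frame(
    name = vapply(records, function(r) r@substrate@name, ""),
    substrate_smiles = subs, product_smiles = prods,
    enzyme = vapply(records, slot, "", "enzyme"),
    class = vapply(records, slot, "", "declaredClass"),
    true_atom = vapply(records, slot, NA_integer_, "trueAtom"),
    stringsAsFactors = FALSE)
  if (is.null(file)) return(df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Structure strings of named fixture compounds
#'
#' Small library of literature compounds used in examples and tests.
#'
#' @return named character vector of SMILES.
#' @export
fixtureSmiles <- function() c(
  amitriptyline = "CN(C)CCC=C1c2ccccc2CCc2ccccc21",
  clomiphene    = "CCN(CC)CCOc1ccc(cc1)C(=C(c2ccccc2)Cl)c3ccccc3",
  metoprolol    = "CC(C)NCC(O)COc1ccc(CCOC)cc1",
  toluene       = "Cc1ccccc1",
  anisole       = "COc1ccccc1",
  phenol        = "Oc1ccccc1",
  ethanol       = "CCO",
  benzene       = "c1ccccc1"
)
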
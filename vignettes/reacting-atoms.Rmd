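---
title: "Predicting reacting atoms of biotransformation reactions"
author: "metaboRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reacting atoms of biotransformation reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboRA)
```

# The problem

Site-of-metabolism prediction often stops at "somewhere around these
atoms". For generating metabolite structures that is not enough: one
needs the *reacting atom* — the single atom, present in both substrate
and product, whose adjacency changed — together with the reaction class,
because each class adds or removes a known fragment at that atom
(hydroxyl for hydroxylations, an oxygen for N-/S-oxidation, carbonyl or
carboxyl formation for C-oxidation, a glucuronyl moiety for
glucuronidations, and loss of an alkyl group for dealkylations, where the
heteroatom left behind is the reacting atom). `metaboRA` covers the nine
classes that dominate human CYP- and UGT-mediated drug metabolism, plus
three merged classes (`hydroxylation`, `all_cyp_reactions`,
`all_reactions`) formed as unions.

The method is purely topological: 2D structure in, ranked atoms out.
Stereochemistry and 3D conformation are deliberately ignored, and no
enzyme mechanism is modelled — the signal is the statistical association
between an atom's local environment and its observed reactivity.

# Identifying reacting atoms from substrate/product pairs

Both structures are parsed to hydrogen-explicit graphs (OpenBabel via
`ChemmineOB`; aromaticity is whatever the parser's model flags, applied
identically in training and prediction). The heavy-atom skeleton of the
smaller structure is embedded into the larger one with VF2, requiring
element equality and adjacency preservation but **ignoring bond orders**
— otherwise every oxidation-state change (C–O vs C=O) would break the
embedding. For each embedding, the atoms of the larger graph outside the
image form the *changed fragment*; embeddings with a disconnected
fragment are discarded (a disconnected graph difference means a
multi-site transformation, which is rejected from training).

An embedded atom is *reacting* when its heavy-neighbour count or its
hydrogen count differs between the two structures. Both signals are
needed: in a hydroxylation the substituted carbon keeps its total degree
(an H is traded for an OH) but changes both heavy-neighbour and hydrogen
counts, while in an equal-heavy-atom-count C-oxidation (alcohol to
carbonyl) only hydrogen counts change and the "embeddings" are the
skeleton isomorphisms. The reported set is the **union over all
surviving embeddings**, so symmetry-equivalent sites (the two ortho
positions of a monosubstituted ring, equivalent methyls of a tertiary
amine) are all labelled — this mirrors how symmetric atoms are labelled
positive together in training data.

Class assignment is a fixed rule table over the direction, the fragment
and the local environment of the reacting atom; glucuronidation is
detected from the fragment structure alone (a six-membered O-heterocycle
of 5 C + 1 O bearing a carboxyl carbon and at least three hydroxyls, 12
heavy atoms), never from names. An enzyme tag constrains plausibility
(UGT only with glucuronidations, CYP isoforms with the other seven);
contradictions are flagged, not fatal. When a record carries a declared
class, it is used as an element hint to filter ambiguous reacting-atom
sets and then checked for consistency — the package's mechanism for the
disambiguation that curated databases achieve with their annotations.

Indexing note: atoms are 1-based everywhere — internally (the natural R
convention) and in all file outputs (the SDF/Molfile convention).

# SoLAs and training sets

A *SoLA* ("structure with one labelled atom") is a molecule plus one
marked heavy atom; it is positive for a class when the marked atom is a
known reacting atom of that class. Two negative-example schemes exist:

* **type 1** — every heavy atom of every substrate is labelled once;
* **type 2** — only atoms of the class's characteristic element (C, N, O
  or S) are labelled, which is the harder, more diagnostic benchmark.

Per class, a substrate's positives are the union of the reacting atoms
over all its records of that class; substrates appearing only in other
classes still contribute all-negative SoLAs. Two assumptions are
documented rather than hidden: (i) an atom not observed to react is
treated as negative (absence-as-negative); (ii) molecules are
deduplicated by identity of their (element sequence, bond table)
representation, which merges repeated records of one substrate parsed
from the same input but does not attempt index remapping between
differently drawn duplicates of the same compound.

# LMNA descriptors

The descriptor grammar is a reconstruction (the original is described
only in earlier literature), versioned as `lmna/1` in every model file so
alternatives can be compared:

* level-0 descriptor of an atom = `[*]["-"]El` — a `*` mark if the atom
  is the labelled atom, a `-` if the atom is in no ring, then the element
  symbol (`"*-C"`, `"C"`, `"-H"`).
* level-n descriptor = level-0 type followed by the lexicographically
  sorted level-(n−1) descriptors of **all** neighbours, hydrogens
  included, in parentheses: methane labelled at carbon gives
  `*-C(-H-H-H-H)` and `-H(*-C)`.

Three design choices matter. First, hydrogens act both as neighbours and
as descriptor origins — the method needs CH2 and CH3 environments to
differ. Second, the `*` mark propagates into neighbours' descriptors
(any atom within *level* bonds of the label "feels" it); without this the
descriptor set would barely depend on the labelled atom beyond radius 0.
Third, formal charge and isotopes are excluded from the atom type to
keep the alphabet small. A SoLA's descriptor set is the set union over
all atoms and levels 1..`maxLevel` (`upto` mode, the default) or the top
level only (`exact`). The default `maxLevel = 2` follows the first- and
second-level neighbourhoods of the original atom-environment literature
and is a configuration knob surfaced in the CLI and stored in model
files. Sorting uses byte order (`radix`), so canonical strings are
locale-independent; canonicality under atom permutation is
property-tested.

Implementation note: the label-free descriptor table of a molecule is
computed once, and per label only atoms within `maxLevel` bonds of the
label are reworked, which makes bulk SoLA description linear in practice.

# The scorer and its degenerate paths

Counts `N`, `N_k`, `N_i`, `N_ik` give the raw frequency estimates
`P(T_k) = N_k/N` and `P(T_k|D_i) = N_ik/N_i` — deliberately unsmoothed,
so the closed-form boundary behaviour is exact (all conditionals 1 gives
B = 1; all 0 gives −1; conditionals equal to the prior give 0). The
defined degenerate paths are:

* a query descriptor with `N_i = 0` (unseen, or vanished after LOO
  exclusion) is skipped and does not count toward `m`;
* if every descriptor is skipped, B = 0 — the information-free score;
* the `S·S₀ = 1` singularity is resolved to B = 0 only when `S` and `S₀`
  are jointly ±1 with the same sign; with `S = 1, S₀ < 1` the formula is
  regular and yields 1;
* arcsine arguments are clamped to [−1, 1] against floating-point drift,
  and B itself to [−1, 1].

Leave-one-out B values are computed *decrementally* — the SoLA's own
contributions are subtracted from the integer counts before evaluation —
which is exactly equivalent to retraining without it; the test suite
asserts this equivalence against scratch retraining.

`P_t(B)` and `P_f(B)` are mid-rank empirical exceedance probabilities
over the sorted LOO B values of the positive and negative examples
(ties credited 0.5). The literature behind the method does not pin down
this estimator; the mid-rank form was chosen because it makes
ΔP = P_t − P_f monotone in B and tie-robust, so rankings by ΔP and by B
coincide — a property the suite asserts. Any monotone-equivalent
estimator leaves IAP and Top-k unchanged, which is the level at which
results are stated. Ranked atoms are ordered by non-increasing ΔP, ties
broken by ascending atom index; Top-k ranking is within one class per
molecule. Models persist as versioned JSON (counts, descriptor
configuration, both LOO B arrays), so prediction needs no training data.

# Validation

IAP is the probability that a random positive example scores a higher ΔP
than a random negative one. The default counts strict inequalities, as
the printed formula does; a tie-aware variant (ties 0.5) equals the
Mann–Whitney AUC and is cross-checked against an independent
implementation in the tests. `crossValidate()` offers leave-one-SoLA-out
and k-fold; **folds partition at the molecule level**, because SoLAs of
one molecule share descriptors and SoLA-level folds would leak — the
conservative choice, flagged here because the source material does not
specify it.

# The synthetic benchmark

The training database behind the original method is commercial, so the
package's benchmark emulates its statistical structure rather than its
content. `generateMolecules()` assembles molecules from a carbon scaffold
(chain of 4–6 atoms or cyclohexane) and 2–4 distinct substituents drawn
from {phenyl, tert-butyl, methyl, ethyl, hydroxyl, methoxy, methylthio,
dimethylamino, methylamino}, hydrogen-filled to standard valences (6–30
heavy atoms). `transformationRules()` implements one edit per elementary
class (e.g. ortho-hydroxylation of a pendant phenyl, O-demethylation of
a methoxy group, N-oxidation of a tertiary amine, glucuronidation at
N–H/O–H). Patterns were designed so that (i) within one molecule a
rule's matches are mutually symmetry-equivalent — at most one amino
substituent is placed per molecule for this reason — keeping ground
truth well-defined under the union-over-embeddings convention, and (ii)
every site is identifiable from its level-2 environment, so the
benchmark carries a learnable structure–label signal by construction.

What the benchmark does **not** emulate: realistic regioselectivity and
electronic effects, competing sites with graded reactivity, tautomers,
counter-ions, stereochemistry, and the long-tailed scaffold diversity of
real metabolite databases. Passing the recovery and parameter-recovery
suites therefore demonstrates that the machinery is correct and that
descriptor-detectable signal is learned and ranked properly — it does
not certify predictive accuracy on real drug metabolism, which would
require the original curated data.

Study conditions used by the suite and chosen once: benchmark of
n = 200 molecules at seed 42 (≈600 records, every class represented),
molecule-level 80/20 holdout for parameter recovery, label-shuffle
negative control judged against the Mann–Whitney null standard error,
and 20 random toy sets (≤30 SoLAs) for the LOO-equivalence oracle. These
sizes give stable statistics while keeping a full test run in minutes on
one core.

# Numerical and policy decisions

* Multi-component inputs (salts, mixtures): keep the largest connected
  component with a warning — metabolite sources store counter-ions, and
  the method operates on one substrate graph. This policy is ours, not
  inherited.
* Equal heavy-atom counts fall back to skeleton isomorphisms with
  hydrogen-count differences (the C-oxidation alcohol-to-carbonyl path).
* Unclassifiable reactions raise a typed condition and are excluded from
  training with a log entry; disconnected graph differences are flagged
  as multi-site and rejected.
* Formal charge cannot survive the MOL2 route used for parsing; a
  valence heuristic restores the common cases (quaternary N⁺, terminal
  O⁻) for display. Descriptors exclude charge and hydrogens are
  materialized before export, so no downstream computation depends on
  it.
* Determinism: every stochastic step (generator, site choice, fold
  assignment, shuffle control) runs under an explicit seed through an
  RNG-state-restoring wrapper, and repeated runs are byte-identical —
  asserted in the tests.

# Known limitations

Tautomer-mismatched substrate/product drawings can defeat the embedding
step (no canonical tautomer handling); multi-step reaction sequences and
atom-mapping strings are out of scope; the deduplication is
representation-identity, not full canonicalization; and the nine rule
patterns cover the benchmark's chemistry, not the full diversity of each
reaction class (e.g. N-dealkylation of larger alkyls is mapped correctly
but never generated). The merged classes are supported throughout but
inherit whatever class imbalance the record set carries.
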
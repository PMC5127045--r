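Package: metaboRA
Title: Reacting-Atom Prediction for Xenobiotic Biotransformation Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the reacting atom of substrate/product pairs for the
    nine major classes of cytochrome P450 and UDP-glucuronosyltransferase
    mediated biotransformations (aliphatic and aromatic hydroxylation, N- and
    O-glucuronidation, N-, S- and C-oxidation, N- and O-dealkylation), learns
    structure-reacting-atom relationships with a Bayesian-like scorer over
    labelled multilevel neighbourhood-of-atoms (LMNA) descriptors, and ranks
    the atoms of new molecules by their probability of being the reacting
    atom. Includes subgraph-isomorphism reaction mapping, training-set
    assembly from structures with one labelled atom (SoLAs), leave-one-out
    and k-fold validation with IAP and Top-k metrics, and a rule-based
    synthetic reaction generator for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
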
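Package: convergia
Title: Quantifying Convergent Evolution in Morphological and Molecular
    Phylogenetic Characters
Version: 0.1.0
Authors@R:
    person("Ada", "Reynolds", email = "ada.reynolds@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify convergent and divergent evolution of
    morphological characters and molecular sites on phylogenies using
    unordered parsimony ancestral-state reconstruction with exact uniform
    weighting over all most-parsimonious reconstructions. Provides
    whole-tree branch-pair convergence/divergence tallies, quartet-based
    convergence/consistency analysis, homoplasy indices (ci, ri, rc), a
    multistate Markov character-evolution simulator with evolutionary
    rates correlated to the number of states, heuristic maximum-parsimony
    tree search with strict consensus and bootstrap support,
    Robinson-Foulds tree comparison, and a filtering pipeline that removes
    convergence-prone characters before total-evidence tree inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn (>= 2.10),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
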
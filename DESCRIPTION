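Package: pbtgsi
Title: Parentage-Based Tagging and Genetic Stock Identification for
    Mixed-Stock Salmon Fisheries
Version: 1.0.0
Authors@R:
    person("Kai", "Larsen", email = "kai.larsen@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic assessment of mixed-stock Pacific salmon
    fisheries from biallelic SNP panels: pairwise-likelihood
    parentage-based tagging (PBT) against fully genotyped hatchery
    broodstocks, a conditional Bayesian mixture model (Gibbs sampler) for
    genetic stock identification (GSI), PBT-first combination of the two
    into stock-composition estimates with conservation-unit roll-up, and
    downstream fishery estimators (catch-weighted seasonal subsampling,
    hatchery-origin catch, coded-wire-tag expansion, exploitation and
    stray rates). Includes a hierarchical F-model simulator of SNP
    baselines, broodstocks, Mendelian offspring and fishery mixtures with
    full ground truth, used for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
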
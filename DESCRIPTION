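Package: OrthoDelta
Title: Gene-Family Decomposition, Gene-Tree Concordance, and the Delta
    Introgression Test
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting ortholog sets from multi-copy gene-family
    trees by tree-based decomposition (single-copy filtering,
    lineage-specific and two-species duplicate trimming, subtree
    extraction, maximum inclusion, and monophyletic-outgroup pruning),
    for quantifying gene-tree discordance against a reference species
    tree via branch-wise gene concordance factors, and for detecting
    introgression from the asymmetry of minor gene-tree topologies with
    the Delta statistic, a gene-tree bootstrap null, and Dunn-Sidak
    multiple-test correction. Includes a duplication-loss and
    multispecies-coalescent simulator with true duplication/speciation
    node labels so every component can be validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape (>= 5.0),
    phytools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
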
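Package: lrrcore
Title: Ortholog Group Analysis of the Plant LRR-RLK Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of the plant leucine-rich-repeat
    receptor-like kinase (LRR-RLK) gene family. Simulates gene families
    evolving by duplication and loss along a tagged species tree, generates
    receptor protein sequences with known extracellular-domain architecture,
    annotates LRR motifs, island domains, Cys-pairs, GDPC cleavage sites and
    hydrophobic signal-peptide/transmembrane segments, reconciles gene trees
    with the species tree and roots them by duplication-loss parsimony,
    extracts monocot/dicot ortholog groups under support and species-count
    thresholds, and post-processes branch-site positive-selection output
    (likelihood-ratio tests, Bonferroni significance coding, Bayes empirical
    Bayes site filtering and site-to-domain accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
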
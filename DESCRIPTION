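Package: linkAC
Title: Link-Based Weighted Associative Classification for Binary Feature Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives per-feature weights from a class-labeled transaction
    dataset (for example compounds described by MACCS/MDL structural key bits
    or dichotomized bioassay readouts) by link analysis on its bipartite
    compound-feature representation, using a unified HITS/PageRank framework
    with a class factor that favours features connected to active compounds.
    The weights drive weighted association rule mining under an adjusted
    weighted support that preserves the downward closure property, and the
    resulting class association rules are ranked and pruned into a CBA-style
    first-match rule classifier. Includes readers and writers for simple
    item-list and fingerprint bitstring formats, k-fold cross-validation,
    weight-vector comparison utilities, a synthetic data generator with
    planted rules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Cheminformatics, GraphAndNetwork, DataImport
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'linkrank.R'
    'warm.R'
    'cba.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
    'dataset-io.R'
    'linkAC-package.R'
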
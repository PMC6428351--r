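Package: phosphoKinNet
Title: Kinase and Phosphatase Regulator Inference from Multi-Strain
    Phosphoproteomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers candidate kinase and phosphatase regulators from
    phosphoproteomic fold-change profiles measured across a strain panel.
    Phospho-peptides are classified by their response pattern across strains,
    partitioned into modules of peptides sharing a phosphorylation motif
    (an iterative binomial-enrichment motif extraction), candidate regulators
    are found as shared interactors of module constituents in a background
    protein-interaction network (hypergeometric test with Benjamini-Hochberg
    correction), and kinase candidates are confirmed by comparing module
    position weight matrices against kinase specificity matrices using
    Kullback-Leibler divergence with a shuffle-based empirical false
    discovery rate. A synthetic-data generator with planted kinase-substrate
    structure supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Network, Proteomics, SystemsBiology, NetworkInference
RoxygenNote: 7.3.3
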
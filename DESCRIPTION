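Package: halogat
Title: Bond Dissociation Energies of Cyclic Hypervalent Halogen Reagents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dataset, cross-halogen correlation analysis, and graph-attention-network
    (GAT) regression for homolytic and heterolytic bond dissociation energies (BDEs)
    of cyclic hypervalent iodine(III), bromine(III), and chlorine(III) reagents.
    Ships DFT-computed BDE tables for five reagent skeletons combined with twenty
    transfer groups, fits the linear dependences between halogen centers by ordinary
    least squares, and trains a from-scratch graph attention network on molecular
    graphs with atomic-descriptor node features (atomic species, empirical partial
    charge, neighborhood composition) to predict BDEs directly from structure.
    Includes a synthetic-data generator with known linear cross-halogen structure so
    every stage of the pipeline is testable independently of the shipped tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
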
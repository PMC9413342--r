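Package: gminet
Title: Co-Expression Networks and Gene-Metabolite Integration for
    Two-Group Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers per-group co-expression networks from paired
    transcriptome and metabolome profiles with the partial correlation
    and information theory (PCIT) algorithm, compares network topology
    between two phenotype groups through hub detection and
    differential-connectivity z-scores, integrates the two molecular
    layers by cross-layer correlation and by a phenotype-interaction
    linear model, and tests feature sets for pathway over-representation
    against user-supplied annotation collections. Ships a synthetic-data
    generator with planted differential expression, group-gated
    co-expression modules and gene-metabolite interaction pairs so every
    stage of the pipeline can be scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
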
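Package: omicarm
Title: Association Rule Mining and Interestingness Measures for Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines association rules among frequently altered genes in
    continuous single- or multi-omics matrices (e.g. RNA-seq expression and
    DNA methylation measured on the same patients). Provides matrix
    discretization into binary molecular-event indicators, exact Apriori
    frequent-itemset mining with the classical support/confidence/lift
    measures, the Lamda3 rule-interestingness measure computed from the
    continuous values rather than the binarized transactions, weighted
    condensed support, two-layer multi-omics combination with cross-omics
    rule filtering, rule network/group-graph exports, and a seeded synthetic
    data generator with planted co-dysregulated gene pairs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
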
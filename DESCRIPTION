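Package: tuba
Title: Tunable Graph-Based Biclustering of Extremal Gene Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers biclusters in gene expression matrices by testing, for
    every pair of genes, whether the samples in their top (or bottom)
    percentile sets overlap more than expected by chance (one-sided Fisher's
    exact test on the hypergeometric overlap). Significant pairs form a
    co-expression graph that is pruned to its triangle-supported core;
    maximum cliques seed biclusters which are then expanded and scored by
    extremal-set enrichment. Includes tuning diagnostics for the two
    adjustable parameters (percentile size and overlap significance cut-off),
    a permutation null, downstream enrichment against sample labels and
    copy-number calls, Hamming-distance clustering of bicluster membership,
    and a synthetic-data benchmark with implanted biclusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    data.table,
    jsonlite,
    graphics,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
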
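Package: corrbic
Title: Correlation-Based Scatter Search Biclustering of Gene Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds biclusters in gene expression matrices with an evolutionary
    Scatter Search over binary-encoded gene/condition subsets. The fitness
    function rewards high average pairwise Pearson correlation among genes,
    so biclusters with shifting and scaling expression patterns
    (g_Y = alpha * g_X + beta) are detected even where the classical mean
    squared residue fails, and an improvement method strips genes that are
    not positively correlated with the rest. Includes a synthetic
    expression-matrix generator with implanted shifting-and-scaling patterns
    and recovery metrics, reporting of per-bicluster quality statistics
    (average correlation, its standard deviation, mean squared residue, gene
    variance, volume), delimited-text matrix input/output, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
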
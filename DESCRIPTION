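Package: coexspec
Title: Differential Co-Expression of Gene Sets via Graph Spectral Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene sets that are differentially co-expressed between
    two phenotypes by comparing the spectral distributions of their gene
    co-expression graphs. For each gene set and phenotype a weighted graph is
    built from pairwise correlation tests (Pearson, Spearman or Kendall, on
    absolute-correlation, 1 - p-value or 1 - FDR-adjusted p-value scales); the
    eigenvalue distributions of the adjacency matrices are estimated by
    Gaussian kernel density and compared by the Jensen-Shannon divergence, with
    significance assessed by permutation of sample labels and
    Benjamini-Hochberg adjustment across sets. Additional graph-distance
    statistics (degree distributions, centralities, clustering coefficients,
    shortest paths, spectral entropy), single-gene differential expression,
    gene rankings, and a Monte Carlo harness for type-I-error and power
    studies on block-correlated synthetic expression data are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
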
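Package: sc3e
Title: Selecting the Best Preprocessing Method for SC3-Style Consensus
    Clustering of Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("sc3e", "developers", email = "sc3e@example.org", role = c("aut", "cre"))
Description: Runs an SC3-style consensus clustering engine on a single-cell
    gene-expression matrix under four candidate preprocessing methods (log2,
    per-gene z-score, no transformation, and a simplified negative-binomial
    Pearson-residual transform) and selects the method whose clustering
    yields the lowest C-score, a graph-based cluster validity index computed
    from the consensus matrix. The C-score is the product of a within-cluster
    weakness term and a between-cluster leakage term read off a contracted
    clustering graph. Includes adjusted Rand index utilities, a clustered
    negative-binomial count simulator for fully offline testing, flat-file
    and Matrix Market readers/writers, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    limma,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
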
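Package: capeRNA
Title: Classification-Based Analysis of Paired miRNA/mRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies differentially regulated miRNA-mRNA interactions from
    paired expression profiles. Each probe's log-normalized expression values
    are discretized into low/medium/high states by maximizing a two-neighborhood
    coverage score over candidate representative pairs and predefined
    fold/neighborhood threshold pairs; probe states are aggregated to genes,
    combined into per-sample interaction states over a nine-state alphabet,
    filtered, and ranked by the pair-counting Jaccard agreement between the
    state-induced sample partition and the experimental groups. Interactions
    can further be filtered by per-group negative Spearman correlation, used to
    build a simple vote-counting classifier evaluated under a bootstrapping
    protocol, and embedded via state substitution, city-block distances, Ward
    clustering and PCA. A synthetic-data generator with planted anti-correlated
    pairs supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
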
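Package: leanet
Title: Local Enrichment Analysis of Gene Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact, exhaustive and parameter-free detection of dysregulated
    local subnetworks in gene or protein interaction networks. For every gene,
    the direct network neighborhood is tested for enrichment of low P-values
    using a binomial order-statistic score, calibrated against an empirical
    size-matched null distribution and corrected for multiple testing by the
    Benjamini-Hochberg procedure. Includes readers for common edge-list
    formats (TSV, SIF, STRING protein links), a simulation harness that
    plants deregulated subnetworks in synthetic scale-free networks, ROC and
    partial-AUC benchmarking utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
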
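Package: phosphonet
Title: Cluster-Filtered and Co-Cluster Correlation Networks from Phosphoproteomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds protein- and site-level signed phosphorylation intensity
    matrices from phosphopeptide quantification tables with explicit handling
    of missing values, ambiguous (conserved-sequence) peptides and inhibitory
    sites; computes missing-data-aware Euclidean, Spearman and hybrid
    Spearman-Euclidean dissimilarities; embeds them with t-SNE and extracts
    clusters by the minimum-spanning-tree single-linkage rule; constructs
    cluster-filtered protein interaction networks (CFN) and co-cluster
    correlation networks (CCCN); evaluates clusters against randomized
    clusters with internal, interaction and GO-enrichment metrics; and
    provides treatment fold-change and organelle-fraction enrichment
    quantitation.  Includes a planted-cluster synthetic data generator so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
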
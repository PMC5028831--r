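Package: ovitx
Title: Comparative Muscle Transcriptome Analysis for Two-Breed RNA-Seq Designs
Version: 0.1.0
Authors@R: person("Ovitx", "Maintainers", email = "ovitx@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for two-condition bulk RNA-seq
    comparisons as used in livestock muscle transcriptomics: RPKM and
    upper-quartile quantification, an empirical-Bayes negative-binomial/Beta
    mixture for differential expression with posterior-probability FDR,
    hypergeometric term enrichment with GO-tree construction, typed
    pathway/gene interaction networks, per-group Pearson co-expression
    networks with k-core hub discovery, and 2^-ddCt qPCR validation.
    Includes a ground-truth-labelled synthetic-data generator emulating a
    two-breed, three-replicate study design so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
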
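Package: methvar
Title: Variably Methylated Gene Discovery and Methylation Signatures from
    Bisulfite Methylation Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering variably methylated genes from per-CpG
    bisulfite methylation call tables and for identifying tissue- and
    location-specific methylation signatures. Implements gene-body
    aggregation under joint coverage qualification, a configurable
    variable-gene selection cascade with a full audit trail, rank-based
    differential methylation (Wilcoxon rank-sum and Kruskal-Wallis) with
    Benjamini-Hochberg false discovery rate control, a run-based scanner
    for localized differentially methylated regions, methylome ordination
    (PCA and classical MDS) with silhouette-based separation scoring,
    annotation enrichment statistics, and a seeded synthetic methylome
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
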
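Package: coregut
Title: Core Gut Microbiota Identification and Co-Abundance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for genus-level core gut microbiota analysis in
    mouse 16S rRNA surveys. Builds genus relative-abundance tables from OTU
    counts with standard quality filters, identifies core genera by prevalence
    across healthy hosts, partitions them into co-abundance groups via Spearman
    correlation under Benjamini-Yekutieli FDR control, tests phenotype
    separation with PCA and one-way MANOVA on ordination scores, screens
    differentially abundant genera with a Kruskal-Wallis plus bootstrapped
    LDA effect-size procedure, correlates principal-component scores with host
    physiological parameters, and reconstructs neighbor-joining phylogenies
    with bootstrap support. Includes a synthetic community generator with a
    machine-readable ground-truth record for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
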
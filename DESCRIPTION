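Package: stellnet
Title: Differential Expression and Network Analysis of TLR4-Dependent
    Hepatic Stellate Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-genotype, multi-treatment
    transcriptomic screens of hepatic stellate cells: empirical-Bayes
    moderated t-statistic differential expression with quantile
    normalization, signed hypergeometric over-representation of gene-set
    collections with Benjamini-Hochberg correction, gene-act-networks
    induced from typed gene-gene relation tables, per-condition Pearson
    co-expression networks with differential-degree and K-core hub
    identification, and four-set Venn partitioning of contrast gene lists
    into receptor-dependent ligand-specific response categories. Includes
    a seeded synthetic-data generator that emulates the two cell line by
    three treatment study design with planted effects, co-expression
    modules, and enriched gene sets, so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    igraph,
    knitr,
    rmarkdown,
    optparse,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
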
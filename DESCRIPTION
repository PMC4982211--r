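Package: metacoman
Title: Comparative Functional Analysis of Metatranscriptomes from Tabular
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a metatranscriptomics analysis pipeline:
    depletion of non-coding-RNA reads by best-hit e-value from BLAST tabular
    (outfmt 6) alignments, best-hit assignment of reads to reference genes,
    relative-abundance profiling over COG/KO/EC annotation systems with
    hierarchical rollup, Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg control and MDS sample ordination, parsimony
    (minimum set cover) pathway inference and gene-set enrichment on fold
    changes, taxonomic contribution/distribution and transcription
    activation analyses, biosynthetic gene cluster activity scoring, and
    Spearman co-expression networks with random-walk community detection.
    Includes a seeded synthetic-data generator with planted signals and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    vegan,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
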
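Package: altox
Title: Divergence Scoring of Aluminum-Stress Transcriptome Responses in
    Contrasting Flax Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for identifying aluminum-responsive and
    aluminum-tolerance-associated genes from a four-genotype (two
    resistant, two sensitive) by two-condition bulk RNA-seq design:
    counts-per-million filtering and trimmed-mean-of-M-values (TMM)
    normalization computed from scratch, per-genotype and pooled-group
    fold changes, a conditional negative-binomial exact test, a
    consistency/delta-score ranking of genes whose aluminum response
    diverges between tolerance groups, Gene Ontology over-representation
    of top gene lists (hypergeometric, with an optional Wallenius
    weighted variant), delta-delta-Ct qPCR cross-validation, and
    phenotype-decline summaries. Includes a negative-binomial count
    simulator with planted gene-response classes so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
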
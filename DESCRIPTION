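Package: rsvr
Title: Sparse Rare-Variant Databases and Bayesian Gene-Disease Association
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building compact relational databases of rare variants
    from cohort sequencing data and for Bayesian inference of gene-disease
    associations. Variants are packed into 64-bit integer identifiers that sort
    by genomic position; Sequence Ontology consequences are stored as
    severity-ordered bitmasks. The association engine compares a baseline model
    against dominant and recessive models with latent per-variant pathogenicity
    over three consequence classes, yielding a posterior probability of
    association per gene and case set. Includes rarity scoring against
    population allele-count references, post-inference filtering, gene-panel
    matching, plausibility scoring, ontology-based phenotype similarity tests
    and a seeded synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    DBI,
    RSQLite,
    jsonlite,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
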
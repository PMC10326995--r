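Package: iqtlkit
Title: Interaction Molecular-QTL Mapping, Direction Calls, Sharing Statistics
    and Mediated Moderation
Version: 0.1.0
Authors@R:
    person("iQTL", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Maps interaction quantitative trait loci (iQTLs) for molecular
    phenotypes (gene expression, DNA methylation) by fitting the linear model
    Y ~ G + E + GxE + C over cis windows, with interaction-aware minor allele
    frequency filters, hierarchical multiple-testing correction (effective
    number of tests per phenotype followed by Benjamini-Hochberg across
    phenotypes), direction-of-effect classification for continuous and binary
    interaction variables, sentinel CpG collapsing, reproducibility and
    sharing statistics (Storey pi1, genomic inflation lambda, normalized LD
    overlap, Haldane-Anscombe odds ratios, allelic concordance), and a
    mediated-moderation analysis (ACME/ADE with BCa bootstrap intervals)
    testing whether trait-by-genotype interactions are transmitted through
    cell-type-proportion interactions. Includes a synthetic cohort generator
    emulating the statistical structure of a multi-ethnic cohort study so the
    full pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
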
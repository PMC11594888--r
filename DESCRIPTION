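Package: popsweep
Title: Selective-Sweep Screening, Mixed-Model GWAS and Marker Statistics
    for Two-Population Resequencing Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of the computational chain used in
    divergent-phenotype whole-genome resequencing studies of livestock: SNP
    quality filtering and functional-consequence annotation, population
    structure via genotype p-distance neighbor-joining trees and PCA on
    standardized genotypes, sliding-window Weir-Cockerham Fst and nucleotide
    diversity with joint top-percentile selective-sweep screening, mixed
    linear model association with a centered kinship matrix, hypergeometric
    term enrichment, candidate-marker population genetics (PIC, heterozygosity,
    Hardy-Weinberg chi-square) with genotype-phenotype association, and
    in-silico PCR-RFLP assay design. Ships a two-population Balding-Nichols
    simulator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
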
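Package: popsweep
Title: Selective-Sweep Scanning and Variant Analysis for Small Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-population whole-genome resequencing
    studies of non-model fish: GATK-style hard filtering of SNP/InDel calls,
    transition/transversion and zygosity summaries, genomic-region and
    coding-effect annotation against GFF3 gene models, sliding-window
    nucleotide diversity (theta-pi) and pairwise Fst selective-sweep scans
    with gene assignment, principal-component and neighbor-joining population
    structure, and relative qPCR expression by the 2^-ddCt method. Includes a
    Balding-Nichols three-population simulator with injected sweeps so the
    whole pipeline is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    ape,
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
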
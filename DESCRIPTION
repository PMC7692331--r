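Package: plastomeVar
Title: Comparative Plastome Variability, Repeat Haplotyping and Bottleneck Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of complete chloroplast genomes
    (plastomes) across a panel of related genotypes: detection of the
    quadripartite LSC/SSC/IR structure, extraction of SNPs and indels from a
    multiple sequence alignment against a reference genotype with functional
    annotation (context, region, coding effect), microsatellite (SSR) and
    perfect tandem repeat detection with cross-genotype repeat-count
    haplotyping, classification of allele-sharing patterns into ancestral,
    lineage-fixed, de novo and diagnostic categories by polarization against a
    distant outgroup panel, domestication-bottleneck diversity statistics, and
    a distance-based phylogeny with bootstrap support. Includes a synthetic
    plastome-panel generator with planted truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Alignment, Phylogenetics, SequenceMatching
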
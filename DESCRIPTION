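Package: dstpanel
Title: Dual-Strand Amplicon Panel Simulation, Consensus Variant Calling and
    Validation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and validating a dual-strand
    amplicon sequencing assay for low-frequency somatic variant detection in
    degraded (FFPE-like) tumour DNA. Models a 16-gene actionable hotspot
    panel tiled by short (<=150 bp) amplicons; simulates strand-specific
    template pools carrying spiked variants, cytosine-deamination damage and
    fragmentation linked to a qPCR quality score (delta-Qc); generates
    paired-end read libraries for each DNA strand; assigns reads to
    amplicons by primer matching, builds per-library pileups and calls
    variants; suppresses single-strand artifacts by dual-library consensus;
    triages samples by delta-Qc and median read depth; and computes
    diagnostic validation statistics (per-base confusion, Wilson score
    confidence intervals, expected-versus-observed allele-fraction
    concordance, cohort summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
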
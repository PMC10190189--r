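Package: gbsmedip
Title: Differential Methylation Analysis for GBS-MeDIP Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for reduced-representation methylome
    sequencing built from restriction-digested, barcoded, antibody-enriched
    libraries (GBS-MeDIP). Covers barcode/remnant demultiplexing, stacked-read
    filtering against a Poisson background, windowed peak calling into regions
    of interest, CpG-coupling calibration and relative methylation scores,
    negative-binomial exact testing of differentially methylated regions with
    Benjamini-Hochberg control, genomic feature annotation with signed TSS
    distances, permutation-based interval overlap testing, and gene-set
    over-representation analysis. Includes a synthetic-data generator that
    emulates PstI-digested, size-selected, methylation-biased paired-end
    libraries with known truth so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
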
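Package: methdomain
Title: Segmentation of Oocyte DNA Methylomes into Hyper- and Hypomethylated
    Domains and Their Correlation with Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a CpG-window segmentation of whole-genome bisulfite
    methylomes into large-scale hypermethylated and hypomethylated domains,
    with exclusion masking (CpG islands, promoters, pre-methylated regions)
    and parent-domain lineage tracking; quantifies the overlap of domains
    with transcription evidence through tiered explanation cascades;
    curates de novo transcriptome assemblies (mono-exonic filtering,
    expression thresholding against size-matched intergenic regions,
    novel-gene and novel-upstream-TSS calling); classifies CpG islands and
    imprinted germline DMRs relative to transcription units; and ships a
    seeded synthetic-data generator with planted truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
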
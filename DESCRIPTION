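Package: bdellotx
Title: Phase-Resolved Transcriptome Dissection of Bdellovibrio bacteriovorus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the dimorphic transcriptome of the
    bacterial predator Bdellovibrio bacteriovorus: per-ORF read counting and
    RPKM-based expression calling with chi-square/Bonferroni differential
    testing, transcription start site (TSS) mapping from paired TAP(+)/TAP(-)
    5'-end libraries, two-box sigma-factor (FliA-like) promoter motif
    discovery and scanning, and coverage-based discovery of attack-phase
    intergenic small RNAs. Includes a synthetic-genome simulator with known
    ground truth (phase-specific gene programs, planted TSSs and promoter
    motifs, planted sRNAs) for end-to-end validation, plus a pipeline driver
    that writes tabular and static-HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
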
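Package: genefamkit
Title: Genome-Wide Gene-Family Characterization Toolkit for AP2/ERF-Type
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for genome-wide characterization of the
    AP2/ERF transcription-factor superfamily: position-specific scoring
    detection of AP2 and B3 DNA-binding domains (with HMMER3 domtblout
    interoperability), architecture-based subfamily classification
    (ERF/DREB/DRF/AP2/RAV/SOLOIST), chromosomal naming and distribution,
    protein physicochemical summaries (molecular weight, isoelectric
    point) and per-column conservation profiles, duplicate-pair detection
    by coding-sequence identity with Nei-Gojobori Ka/Ks estimation and
    selection calls, neighbor-joining phylogenies with bootstrap support
    and clade assignment, repression-motif and promoter cis-element
    scanning, and expression analysis of FPKM matrices and qPCR Ct tables
    (tissue-specificity tau, stress response calls, 2^-ddCt). A bundled
    synthetic-genome simulator with recorded ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
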
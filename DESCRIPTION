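Package: atacscreen
Title: Integrative ATAC-seq and RNA-seq Screening for Upstream
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying transcription factors that regulate a
    target gene by integrating chromatin accessibility (ATAC-seq) with
    gene expression (RNA-seq) across a patient cohort. Implements
    cohort-consensus open-chromatin region calling, strand-aware promoter
    assignment and feature annotation, overlap-weighted accessibility
    quantification, a correlation screen of an inflammatory transcription
    factor panel (NF-kB, IRF and STAT families) against promoter
    accessibility with Benjamini-Hochberg false-discovery control,
    position-weight-matrix motif scanning, permutation-based ChIP-seq
    peak overlap testing, single-sample rank-based gene-set scoring with
    a dual-correlation filter, and a synthetic-cohort generator with a
    planted regulator for offline validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
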
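Package: atacdeck
Title: Post-Alignment Quality Assessment and Preprocessing of ATAC-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality assessment and preprocessing toolkit for aligned
    paired-end ATAC-seq data. Computes alignment filtering and duplication
    metrics (mitochondrial fraction, duplicate rate, NRF, PBC1/PBC2),
    fragment-size distributions, Tn5 cut-site shifting (+4/-5),
    nucleosome-class fragment binning with in-silico splitting of di- and
    tri-nucleosome fragments, TSS-centred signal matrices and average
    profiles, transcription-factor footprint profiles from position
    frequency matrices, library-complexity extrapolation (Good-Toulmin /
    zero-truncated negative binomial), and peak-based saturation analysis
    with a minimal internal Poisson window peak caller. Includes a
    synthetic-data generator producing paired-end BAM libraries with known
    ground truth so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    digest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
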
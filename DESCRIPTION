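Package: ChIPregulon
Title: Windowed-Enrichment ChIP-Seq Peak Calling and Pseudo-Palindromic
    Regulon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for characterising a bacterial
    transcription-factor regulon from ChIP-seq coverage and downstream
    binding assays. Implements a sliding-window enrichment peak caller
    with a negative-binomial null and Benjamini-Hochberg correction,
    mismatch-tolerant scanning for inverted-repeat (pseudo-palindromic)
    binding sites with variable linker lengths, IUPAC consensus
    construction, genus-wide regulon conservation scanning with a
    reciprocal best-hit orthologue screen, steady-state surface plasmon
    resonance affinity analysis (theoretical Rmax, percent Rmax, one-site
    Langmuir fits, effector classification), and qPCR quantification
    (2^-ddCt relative expression and standard-curve absolute
    quantification). Ships a synthetic-data generator with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    minpack.lm,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
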
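Package: medseqr
Title: MeD-Seq cfDNA Methylation Scoring Against a Healthy-Donor Reference Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-level processing of methylation-dependent restriction enzyme
    (LpnPI) sequencing data from cell-free DNA: in silico digestion and cohort
    simulation, adapter trimming, the 13-17 bp restriction-site read filter,
    unique placement and per-site counting, summarization into 2 kb windows
    around transcription start sites, empirical-Bayes moderated-t differential
    methylation with Benjamini-Hochberg FDR, a reference-panel Z-squared-sum
    methylation score with a healthy-donor positivity cutoff, and survival
    association of the score (Kaplan-Meier, log-rank, Cox proportional
    hazards).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
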
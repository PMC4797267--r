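Package: occudiff
Title: Differential ChIP-Seq Occupancy Analysis for Two-Condition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing protein-DNA occupancy between two ChIP-seq
    conditions, built around a windowed read-count comparison at peak centers
    with an exact binomial test and inclusive fold-change/p-value thresholds
    that classify sites as induced, repressed, or common. Includes
    strand-aware annotation of sites into seven genomic categories (promoter,
    TTS, 5'/3' UTR, exon, intron, intergenic) with log-space binomial
    ("Bernoulli") enrichment tests that remain exact far below double
    underflow, position-weight-matrix motif scanning with per-class
    motif-occurrence fractions against a sampled genomic background, a
    minimal sliding-window peak caller, bench-assay statistics (chromatin
    fractionation percentage, percent survival, paired t-tests), and a
    seeded two-condition read simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
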
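Package: circasplice
Title: Circadian Alternative Splicing Detection from Probe-Level Exon Arrays
Version: 0.1.0
Authors@R:
    person("Maintainer", "circasplice", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A probe-level exon-array analysis toolkit for discovering
    circadian regulation of alternative splicing from short time courses.
    Implements quantile normalization, per-transcript-cluster median-polish
    (RMA-style) probe models, FIRMA splice-departure scores, a circadian
    rhythmicity screen (one-way ANOVA with optional empirical-Bayes variance
    moderation, Benjamini-Hochberg FDR control, and an antiphase contrast
    that excludes 12-hour ultradian signals), temporal-profile phase metrics
    and self-organizing-tree clustering, quantitative-PCR validation
    arithmetic, clock transcription-factor motif scanning with Fisher
    enrichment tests, and reading-frame classification of cassette-exon
    skipping for nonsense-mediated decay candidacy. Includes a seeded
    synthetic probe-level data generator with planted ground truth so the
    whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
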
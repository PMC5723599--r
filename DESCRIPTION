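Package: spacerprime
Title: Clade-Specific Primer Design and In Silico PCR for the rDNA ITS Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and evaluating clade-specific PCR primers
    targeting the nuclear ribosomal Internal Transcribed Spacer (ITS) region.
    Annotates rDNA cassettes (partial 18S, ITS1, 5.8S, ITS2, partial 28S)
    using conserved sequence landmarks, discovers conserved primer-candidate
    windows in multiple sequence alignments, screens degenerate primer pairs
    by mismatch-tolerant in silico PCR, and aggregates taxon-partitioned
    specificity tables. Includes a synthetic rDNA cassette generator with
    planted ground truth for validation, modeled on clitellate (Annelida)
    ITS architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
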
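Package: siestacline
Title: Sleep, Activity Rhythm, and per 3' UTR Haplotype Analysis for
    Drosophila Clinal Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for clinal variation in the Drosophila
    melanogaster mid-day siesta. Reads Trikinetics-style activity monitor
    data, annotates sleep bouts (5 contiguous inactive minutes), computes
    fragmentation metrics (median sleep bout length, bout counts) in 4-h
    windows with boundary clipping, builds normalized startle-corrected
    daily activity profiles, estimates free-running periods with a
    chi-square periodogram, classifies period-gene 3' UTR haplotypes from
    sequence, quantifies dmpi8 intron splicing efficiency from gel band
    intensities, and runs the tropical-versus-temperate contingency and
    group-comparison statistics. Includes stochastic generators for
    activity records, UTR sequences, and gel quantifications so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
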
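Package: mfscreen
Title: Chromosome-Quotient Screening for Male-Determining Factor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the chromosome-quotient (CQ) screen
    used to discover male-determining (M) factor candidates in culicine
    mosquitoes. Per-transcript male and female genomic alignment counts are
    turned into CQ statistics and filtered for male specificity; TMM
    (trimmed mean of M-values) normalization and a staged presence/absence
    expression filter across embryonic and adult samples form the second
    gate; transposase/reverse-transcriptase-like contigs are excluded by
    annotation. Also provides candidate characterization (longest-ORF
    finding, translation, in-silico PCR), knockout-phenotype summary
    statistics (feminization percentages, injection/hatch/sex-ratio tables,
    2^-ddCt fold changes), and a synthetic-data generator that plants
    hemizygous male-specific, autosomal and female-dosage-biased contigs so
    the whole screen is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
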
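Package: entomocomp
Title: Comparative Genome Annotation Analyses for Entomophthoralean Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses of fungal genome annotations built around the giant,
    repeat-rich genomes of entomophthoralean insect pathogens: sliding-window
    detection of repeat-induced point mutation (RIP) via composite dinucleotide
    indices, cross-species protein-domain enrichment by pairwise Fisher exact
    tests with fold-versus-median summaries, rule-based classification of
    proteins by Pfam domain architecture (circadian, light-sensing, RNAi and
    RID-like candidates), orthogroup occupancy and species-specific gene
    accounting with expression filtering, and repeat-divergence landscape
    summaries under the Kimura two-parameter model. Includes seeded synthetic
    data generators with planted ground truth so every analysis stage can be
    exercised end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
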
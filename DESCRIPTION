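Package: crassrecruit
Title: Fragment Recruitment Analysis of crAss-Like Phages in Viromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for metagenomic fragment-recruitment analysis of
    bacteriophage genomes in viromes, built around the workflow used to
    identify human-specific crAss-like phages: filtering of tabular
    read-vs-genome alignments (query coverage, e-value, best hit),
    per-genome recruitment statistics (sequencing depth, SD/Gbp/Kbp
    normalized abundance, average nucleotide identity of mapped reads,
    horizontal genome coverage), a human-vs-animal specificity decision
    rule on horizontal-coverage matrices with an exact Mann-Whitney U
    test, VIRIDIC-style intergenomic similarity with species/genus
    threshold clustering, country-level biogeographic aggregation, and a
    virome read simulator with recorded ground truth for end-to-end
    validation without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
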
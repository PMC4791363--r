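Package: thermopop
Title: Recovery and Characterization of Microbial Populations from
    Hot-Spring Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for recovering genome populations from
    thermal-spring "streamer" community metagenomes and characterizing
    them: tetranucleotide word-frequency PCA binning of contigs refined by
    G+C content and coverage, read recruitment at a nucleotide-identity
    threshold with per-bin abundance and G+C histograms, marker-catalog
    completeness estimation, a seeded local-alignment engine with
    fragment-based average nucleotide identity (ANI), bidirectional
    best-hit average amino-acid identity (AAI) and 16S rRNA identity,
    weighted concatenated marker-gene distance phylogenies with bootstrap
    support and conserved signature indel scanning, COG presence/absence
    NMDS ordination and pathway completeness scoring, and 16S
    identity-threshold occurrence calling across site surveys with
    rank-sum statistics. Includes a synthetic-community generator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    stats,
    utils,
    withr,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
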
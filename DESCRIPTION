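Package: levitax
Title: Taxonomic Classification of Bacteria-Infecting ssRNA Phages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for identifying and classifying bacteria-infecting
    positive-sense single-stranded RNA viruses (class Leviviricetes) from
    genome assemblies. Calls open reading frames, detects the three core
    proteins (maturation protein, coat protein and RNA-directed RNA
    polymerase) with profile hidden Markov models, groups proteins by
    Markov clustering of an all-vs-all similarity graph, assigns orders
    and families from cluster membership with an incongruence rule, and
    demarcates genera and species by pairwise amino-acid identity (PAAI)
    clustering of the polymerase at 50 and 80 percent. Includes a
    neighbor-joining tree builder with clade-concordance reporting, a
    HMMER3 ASCII reader/writer, and a synthetic genome simulator with
    planted taxonomy for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
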
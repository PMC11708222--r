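Package: allelegeo
Title: Marker-Gene Allele Typing, Geographic Dispersal, and Single-Gene
    Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: IUPAC-ambiguity-aware genotype calling at diagnostic codon
    positions of a coding sequence, detection of repeat-flanked internal
    deletions and frameshift truncations, grouping of isolates by composite
    genotype, geographic dispersal statistics for allele groups, and
    single-gene neighbor-joining phylogenies from uncorrected p-distances
    with clade-concordance scoring.  Includes a synthetic sequence-panel
    generator with planted ground truth so every pipeline stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    geosphere,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
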
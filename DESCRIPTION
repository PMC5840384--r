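Package: radmap
Title: Outcross Linkage Mapping and Comparative Placement of RAD Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps for full-sib outcross (CP) families
    genotyped with RAD-seq markers. Classifies marker cross types (ab x ab,
    ab x ac, ab x cd), filters markers on Mendelian segregation and presence,
    estimates pairwise recombination fractions with parental phase by maximum
    likelihood, groups markers at a LOD threshold, orders them by minimising
    the sum of adjacent recombination fractions, and converts distances with
    the Kosambi map function. Downstream tools detect conserved synteny and
    collinearity between the map and reference genomes from tabular homology
    hits, and infer map intervals for unplaced transcripts from the nearest
    flanking markers inside collinear blocks. A simulation module generates
    ground-truthed families, rearranged reference genomes and transcript hit
    tables so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
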
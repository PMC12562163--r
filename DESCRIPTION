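Package: ssrpopgen
Title: Microsatellite Mining, Polymorphism Screening and Population Genetics for Codominant SSR Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects perfect microsatellites (SSRs) in nucleotide sequences with
    MISA-style per-motif-size repeat thresholds, canonicalizes motifs under
    rotation and reverse complement, groups compound SSRs, and tabulates census
    statistics. Screens candidate polymorphic loci by masking repeats, filtering
    short flanks, greedy identity/coverage clustering of masked sequences and
    per-cluster length-polymorphism scoring. Computes codominant diploid
    diversity indices (Na, Ne, Shannon I, Ho, He, PIC, inbreeding F) with
    Hardy-Weinberg tests, pairwise Weir-Cockerham Fst with island-model gene
    flow Nm, Nei (1972) standard genetic distance, UPGMA dendrograms, allele-level
    AMOVA, principal coordinates analysis, and Evanno delta-K post-processing.
    Includes a Balding-Nichols genotype simulator and a planted-SSR sequence
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
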
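Package: stopswitch
Title: Detection and Phylogenetic Analysis of Mitochondrial Stop-Codon
    Readthrough Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect stop-switch substitutions and stop-codon
    readthrough extensions in mitochondrial genes (the short/long ND6
    length polymorphism of camarodont sea urchins is the motivating
    case), compute the resulting opposite-strand gene overlaps, map the
    short/long character on a phylogeny with a generalized Fitch
    parsimony that handles polymorphic tips, assess consistency with
    trans-species polymorphism, and test RNA-editing and
    codon-reassignment alternatives by DNA-versus-transcript read
    concordance. Ships alternative mitochondrial genetic-code tables
    (including the echinoderm code in which TGA encodes tryptophan), a
    seeded synthetic-data generator with known ground truth, and
    physicochemical protein comparisons (amino-acid composition,
    Kyte-Doolittle hydrophobicity, Grantham distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
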
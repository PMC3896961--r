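Package: tripletWD
Title: Triplet-Weight Graphical Representation and Weight-Deviation
    Similarity of DNA Coding Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free comparison of DNA coding sequences via a
    triplet (codon) weighting scheme. Each of the 64 DNA triplets carries a
    real-valued weight whose integer part indexes the encoded amino acid and
    whose fractional part distinguishes synonymous triplets; a coding
    sequence becomes a 2D plot set of (position, weight) points, and two
    sequences are compared by the weight deviation, a weighted L1 distance
    between their 64-long triplet count vectors divided by 64. Ships the
    11-species beta-globin coding-sequence benchmark, pairwise
    distance-matrix construction with CSV/PHYLIP output, UPGMA and
    neighbor-joining tree building with Newick export, a seeded random
    coding-sequence generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
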
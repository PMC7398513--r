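Package: fawtype
Title: Marker-Based Strain Typing and Population Comparison of Fall Armyworm
Version: 0.1.0
Authors@R:
    person("FAW", "Typing Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies fall armyworm (Spodoptera frugiperda) specimens into
    host-strain and haplotype categories from COI and Tpi amplicon sequences,
    using diagnostic single-nucleotide sites located by anchored alignment to
    bundled reference segments. Builds per-population haplotype frequency
    profiles and compares populations via haplotype diversity (Hd), nucleotide
    diversity (Pi), Hudson-style pairwise Fst, Pearson correlation of
    frequency profiles, and Tamura-Nei (TN93) distance neighbor-joining trees.
    Includes a synthetic-data generator that emits specimen collections with
    known ground truth so the whole pipeline is testable without sequence
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
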
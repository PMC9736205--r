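Package: gelpscan
Title: Two-Entropy Alignment Scanning and Docked-Pose Geometry for
    Transferase-Specific Residues in GDSL Esterase/Lipase Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating amino-acid residues that distinguish
    transferase-active members of the GDSL esterase/lipase (GELP) family
    from the hydrolase background. Implements a two-entropy scan of a
    group-labelled multiple sequence alignment with BLOSUM62 pseudo-count
    regularisation, ranking of columns preferentially conserved in the
    transferase group, an esterase-absence filter, sequence status
    classification and phylogenetic tip annotation; plus a geometric
    "reasonable model" counting statistic over docked substrate poses
    around a catalytic triad, summarised per protein variant and compared
    against the native enzyme with a Monte-Carlo Dunnett many-to-one test.
    Seeded simulators for labelled alignments with planted group-specific
    columns and for receptor/pose coordinate sets make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
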
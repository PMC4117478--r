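Package: capscape
Title: Identification and Quantification of 5' Cap Structures on Short RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the 5' cap landscape of short (<200 nt)
    RNAs from three complementary assays. Provides exact elemental-composition
    algebra and monoisotopic mass computation for methylated 5'-5' cap
    dinucleotides, combinatorial enumeration of candidate cap structures,
    ppm-tolerance assignment of LC-MS observed anion masses to isobar groups,
    and cap-type classification; small-RNA sequencing utilities (3' adapter
    clipping with insert-length inference, rRNA dusting, a toy exact-match
    aligner, EcoP15I-style CAGE tag truncation); hierarchical priority-resolved
    biotype annotation with length-range composition tables, TSS/TTS window
    profiles and tag-cluster enrichment; normalization of 2D-TLC spot
    densitometry into replicate-summarized percentages; and seeded synthetic
    data generators (genome, annotations, four library types, mass
    observations, spot tables) with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
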
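Package: introdissect
Title: Genomic Dissection of Introgression Sub-Lines from Dual-Reference Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to dissect the genome of an introgression sub-line carrying a
    homozygous chromosomal segment from a wild donor species in a cultivated
    background. Classifies per-gene ancestry from variants called against both
    parental reference genomes, localizes introgression breakpoints (down to an
    intra-gene recombination point from Sanger-style multi-alignments),
    reconstructs the hybrid genome with lifted-over gene models, reconciles
    orthology between the replaced and introgressed gene sets via best
    bidirectional hits, evaluates SCAR/CAPS markers in silico, and summarizes
    differential-expression tables against the introgressed region. Includes a
    synthetic-data generator producing parental genome pairs with a planted
    introgression and a machine-readable truth record for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
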
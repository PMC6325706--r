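Package: ylink
Title: Y-Linked Contig Assignment, Gene Conversion, and Repeat Landscapes
    from Male/Female Sequencing Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying heterochromatic, Y-linked sequence in
    assemblies of species with heteromorphic sex chromosomes. Partitions
    read alignments into heterochromatin-enriched subsets, assigns contigs
    and windows to the Y, X, or autosomes from the median per-site
    female-to-male depth ratio (with the chromosome quotient as a
    comparator), estimates gene-conversion rates in Y-linked multicopy gene
    families (four-gamete Rmin, an LD-based population recombination
    parameter, and similarity-based rates), summarizes RepeatMasker and
    Tandem Repeats Finder annotations per chromosome group with
    whole-chromosome extrapolation, and ships a synthetic-data module so the
    entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
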
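Package: structscore
Title: Per-Nucleotide RNA Secondary Structure Scores from High-Throughput Probing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-nucleotide RNA secondary-structure scores from the four
    major high-throughput structure-probing assay designs (PARS, DMS-seq, icSHAPE
    and ds/ssRNA-seq), starting from aligned reads. Provides strand-aware 5'-end
    and full-read coverage counting with the standard post-alignment read filters,
    the method-specific scoring equations, an in-memory genomic-interval score
    store with half-open coordinate queries, strand-aware aggregation of scores
    across collections of equal-length regions into meta-profiles, harmonized
    display transforms (scaling, re-centering, reactivity inversion), an IUPAC
    motif scanner, and seeded simulators of hairpin-shaped probing data for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
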
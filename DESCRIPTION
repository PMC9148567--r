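Package: xic5c
Title: Analysis of 5C Contact Maps for Structurally Rearranged Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and differential analysis of chromosome conformation
    capture carbon copy (5C) contact maps of the mouse X-inactivation centre
    and of alleles carrying structural rearrangements (inversions, deletions).
    Implements replicate pooling and total-count normalisation, outlier and
    singleton filtering, running-median binning, a neighbourhood
    coefficient-of-variation noise mask, distance-stratified z-score maps and
    differential maps, virtual-inversion coordinate remapping and
    deletion-aware distance adjustment, insulation-score profiles with trough
    (TAD boundary) calling, and the accompanying expression statistics
    (nCounter-style control normalisation, paired t-tests, Mann-Whitney tests
    on allelic ratios).  A synthetic-data module simulates 5C maps with
    programmed TADs and orientation-dependent CTCF loops, ligation-junction
    reads, expression count tables and per-embryo allelic ratios, so that
    every stage of the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
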
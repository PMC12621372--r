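Package: diagpart
Title: Diagonal Partitioning for Balanced Gapped Extension in Pairwise
    Genome Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for balancing the gapped-extension stage of
    seed-filter-extend pairwise genome alignment. Oversized segment files of
    high-scoring ungapped pairs (HSPs) are split into contiguous diagonal
    bands so that anchors lying on the same alignment stay in the same
    extension job, avoiding the duplicate and extra ("straddling")
    alignments created by naive row-wise splitting. Includes adaptive
    upper-quartile partition sizing, longest-processing-time-first
    chromosome binning, a compressed "keg" archive bundling partition files
    with their batch of extension commands, a deterministic parallel batch
    runner with MAF concatenation, and a desk-scale toy aligner (sequence
    pair simulator, exact k-mer seeding, x-drop gap-free extension, y-drop
    banded affine-gap extension with anchor-crossing suppression) that makes
    partitioning quality measurable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
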
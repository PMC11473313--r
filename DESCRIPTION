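Package: fusionrec
Title: Case-Control Discovery of Hereditary and Epigenetic Fusion Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies RNA-seq fusion-transcript junctions as readthrough
    (epigenetic) or genomic-rearrangement products from gene annotation
    geometry, collapses per-run fusion calls to unique patients, tests
    case-control recurrence with a pooled two-proportion Z-test behind an
    n*p >= 5 recurrence filter, models the probability that recurrent
    fusions arise somatically, validates calls by exact junction-probe
    scanning of FASTQ reads, and simulates annotations, cohorts, and reads
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    withr,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
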
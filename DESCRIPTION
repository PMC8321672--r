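Package: pipstruct
Title: RNA Structure Scores and Protein-Protected Site Calling from
    Nuclease Footprinting Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired nuclease footprinting libraries
    (protein-bound "footprint" and protein-stripped "structure-only"
    ssRNase/dsRNase digestions) along the erythroid differentiation time
    course of MEL cells. Computes per-base generalized-log (glog) RNA
    secondary structure scores with transcript-mean normalization, calls
    protein-protected sites (PPSs) by per-base Poisson enrichment of
    footprint over structure-only coverage with genome-wide
    Benjamini-Hochberg false discovery control, and provides the
    downstream toolkit: metagene profiles around start and stop codons,
    ribosome-size filtering and replicate intersection, greedy genomic
    annotation, matched background shuffling, overlap and conservation
    enrichment, structure-change partitioning and clustering, PWM
    log-odds motif scanning, and iBAQ pulldown enrichment. A
    ground-truthed synthetic-data generator emulates the library design
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
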
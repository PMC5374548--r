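Package: pairedqc
Title: Quality Control, Filtering and Overlap-Based Error Correction for
    FASTQ Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quality control and preprocessing for single-end and
    paired-end FASTQ data. Computes per-cycle base-content and quality
    profiles, per-cycle discontinuity and k-mer strand-bias diagnostics;
    derives a single global (front, tail) trim for a whole file from the
    cycle profile; filters reads by quality, N content and error-tolerant
    polyX detection; detects flowcell air-bubble artifacts from the spatial
    distribution of polyX reads and blacklists the affected regions. For
    paired-end data, an edit-distance-minimising offset search finds the
    overlap of each read pair, cuts read-through adapters at negative
    offsets without any adapter sequence input, corrects quality-asymmetric
    mismatches in the overlap, estimates the sequencing error rate and the
    base-transform spectrum from overlap mismatches, and can merge pairs
    into high-quality single-end reads. Includes a fixture simulator with
    full ground truth and a batch pipeline producing JSON and static HTML
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
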
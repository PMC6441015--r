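Package: poredose
Title: Synthetic Nanopore Runs and Dose-Response Sequencing Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how ionizing radiation degrades nanopore
    sequencing performance. Simulates flow-cell runs at event resolution
    (k-mer pore model, stay/skip/step translocation moves, basecall error,
    dose-dependent pore death and current drift, 2048-well/512-channel MUX
    rotation), computes the standard event-level quality metrics (read
    length, skips per base, stays per base, time-chunked series), aligns
    reads to a reference with a built-in banded semi-global aligner
    (percent aligned, base identity, genome coverage, barcode
    demultiplexing), emulates the platform quality control that counts
    active pores, and assembles per-dose summaries compared against the
    worst-performing unirradiated control, together with the dosimetry
    arithmetic (roentgen to gray(Si), dose-rate accumulation, mission
    transit doses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
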
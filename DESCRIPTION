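Package: didaseq
Title: UMI Consensus Error Correction and ctDNA Quantification for
    Dual-Indexed Degenerate Adapter Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-indexed degenerate adapter (DIDA) sequencing
    libraries for circulating tumor DNA (ctDNA) monitoring. Demultiplexes
    paired-end reads by fixed sample index, extracts degenerate molecular
    barcodes (UMIs), groups tagged aligned reads into molecule families and
    collapses them into single-strand consensus sequences (SSCS) with
    end-masking, mate-overlap collapsing and an index-hopping/tag-swap
    duplicate filter. Builds a panel-wide background error model from pooled
    negative-control pileups with an exact binomial upper confidence bound,
    performs binomial detection of patient-specific tumor mutations at
    allele fractions down to 0.01 percent, converts allele fractions to
    mutant genomes per mL plasma, and computes per-timepoint limits of
    detection. Includes a synthetic library generator (template molecules,
    PCR jackpot errors, sequencing errors, index hopping, dilution series)
    so every stage is testable without external data, and tools for
    selecting patient-specific mutation panels from tumor variant calls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
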
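Package: mhcamp
Title: Amplicon Genotyping and Evolutionary Analysis of Highly Duplicated MHC Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for genotyping extremely duplicated MHC
    class I genes from tagged amplicon reads and for the comparative evolutionary
    analysis of the resulting allele sets. Covers dual-barcode demultiplexing,
    per-amplicon variant tables, artifact filtering (low-copy, PCR-chimera and
    1-2 bp error variants), replicate-verified allele calling with expression
    classification, partition of exon-3 alleles into in-frame deletion length
    classes, diversity and divergence statistics, site-wise positive-selection
    tests with a k-of-m consensus rule and subsampling randomization,
    recombination scans (MaxChi, Chimaera, PHI) with consensus calls, and
    NeighborNet split networks with non-negative least-squares split weights and
    bootstrap supports. A synthetic amplicon-read generator with full provenance
    makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
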
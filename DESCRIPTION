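Package: centwave
Title: Wavelet-Based Centromere Identification from Chromosome Density
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates putative centromeres on assembled chromosomes by
    continuous wavelet transform (Ricker wavelet) of windowed genomic
    density signals (DNA methylation read counts, SNP density, gene-body
    coverage, assembly gaps), detecting the characteristic broad
    pericentromeric coefficient peak containing a narrower centromeric
    valley.  Also implements the allele-specific Custom Correlation
    Coefficient (CCC) for SNP co-segregation across a population,
    including site filtering, block-pair job scheduling and gene-anchored
    co-evolution density profiles, plus a synthetic-data generator with
    planted centromere signatures and linkage-disequilibrium blocks for
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
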
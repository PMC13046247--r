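Package: meiocal
Title: Spike-In Calibrated ChIP-Seq Analysis of Meiotic Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spike-in calibrated ChIP-seq analysis of proteins bound
    to meiotic chromosomes, as used to map crossover-pathway factors against
    double-strand-break hotspots, chromosome axis sites and centromeres in
    budding yeast. Implements scaling-factor calibration against a related
    spike-in species, 10-bp binned coverage tracks with untagged-control
    subtraction, replicate averaging and Gaussian kernel smoothing, a
    self-contained local-Poisson peak caller, Venn-style peak classification
    against feature maps, and the comparative statistics used in such studies
    (rank-sum tests, chromosome-size binding density, hotspot-strength
    comparisons, SNP-density and crossover co-occupancy analyses). A seeded
    synthetic-data generator emulates the statistical structure of the
    experiment so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
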
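Package: swapCGH
Title: Dye-Swap Array-CGH Copy-Number-Variation Calling Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-color dye-swap array comparative genomic
    hybridization (aCGH) copy-number analysis: spot and region quality control,
    weighted-loess MA normalization, a per-spot linear model that estimates and
    removes spot-specific dye bias from balanced dye-swap designs, circular
    binary segmentation with permutation significance, copy-number-variant
    region (CNVR) calling by the consecutive-probe rule with flank extension,
    cross-sample union merging, genomic-interval coverage accounting and
    random-interval permutation tests against feature sets, hypergeometric
    gene-set over-representation with Benjamini-Hochberg adjustment, and an
    expression-consistency re-analysis (probeset collapsing, per-gene t-tests at
    a relaxed FDR). A synthetic-data module simulates diploid genomes with
    planted gains and losses, tiled probe layouts, and dye-swap hybridizations
    with spot-specific dye bias, spatial gradients and lognormal intensity
    noise, so every stage is testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
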
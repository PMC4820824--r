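Package: chipdissect
Title: Confound-Aware Dissection of Genome-Wide Protein-DNA Binding Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how genome-wide ChIP-seq binding signals
    relate to DNA sequence composition and cytosine methylation while
    controlling for the strong mutual correlations among GC content, CpG
    density and methylation density. Implements signal-extraction-scaling
    (SES) normalization of ChIP against Input, coverage-weighted binned
    methylation density estimation from per-cytosine calls, marginal and
    partial correlations with conditional (GC, CpG) enrichment maps,
    Gaussian graphical models over binned genome tracks, random-forest
    prediction of binding from reverse-complement-collapsed k-mer
    frequencies with ROC/equal-error-rate evaluation and tree-depth feature
    importance, GO-aggregated differential expression with empirical
    expression-dependent dispersion, metagene alignment heat maps, and a
    fully controlled synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    ranger,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
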
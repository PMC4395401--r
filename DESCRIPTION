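Package: rilmap
Title: SNP-Array Genotype Calling and Ultra-Dense RIL Linkage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-color SNP genotyping
    arrays applied to recombinant inbred line (RIL) populations. Includes a
    population and hybridization-signal simulator (Haldane crossover model,
    selfing to F7, Gaussian signal clusters with array, probe and spatial
    artifacts), nearest-neighbor melting-temperature probe design, signal
    preprocessing (quantile normalization, per-probe centering, spatial
    defect masking, median-polish replicate summarization), training-set
    based Mahalanobis genotype calling with confidence scores, marker and
    sample filtering (redundancy, low-confidence, segregation
    goodness-of-fit), binned Haldane linkage-map construction, rule-based
    genotype refinement along the map, and genome scans for local
    recombination rate, segregation distortion and map-genome collinearity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
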
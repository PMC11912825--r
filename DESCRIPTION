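Package: spikemimic
Title: Design and Quantitative Use of Synthetic rRNA-Operon Spike-In Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing synthetic rRNA-operon spike-in standards
    ("rDNA-mimics") for absolute quantitative amplicon sequencing of fungal,
    eukaryotic and bacterial microbiomes, and for turning spiked ASV count
    tables into absolute microbial loads. Includes a constrained random
    sequence designer (homopolymer, repeat, GC-uniformity, prohibited k-mer
    and local-alignment screens over progressively assembled 20-mers), an
    operon scaffolder that substitutes artificial variable regions between
    primer-anchored conserved blocks with in-silico PCR validation,
    additive-log-ratio based load estimation with differential loads and
    bacterial-to-fungal ratios, standard-curve and dose-response quality
    control, and a simulator of spike-in experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    vegan,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
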
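Package: minisplice
Title: Quantification, Specificity Scoring and Generative Design of
    Minigene Splicing Reporter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for massively parallel splicing reporter
    (minigene MPRA) experiments that measure cassette-exon inclusion across
    cell types. Provides library design (exon filtering, intron trimming,
    barcoding, saturation mutagenesis), quantification of barcoded paired-end
    amplicon reads into UMI-deduplicated isoform counts and percent-spliced-in
    (PSI) matrices with chimeric-read correction, cell-type specificity
    indices (Tau and the PSI-adapted Upsilon) with shortlisting rules,
    mutation-sensitive region calling from saturation mutagenesis effect
    maps, a residual convolutional network that predicts PSI from sequence
    and cell-type expression profiles, and a teacher-guided variational
    autoencoder that designs sequences with programmable splicing outcomes.
    A synthetic-data module simulates every input, including a ground-truth
    sequence-to-PSI oracle, so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
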
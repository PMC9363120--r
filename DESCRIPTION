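Package: fragsig
Title: Fragment Length Signature Deconvolution for Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised deconvolution of cell-free DNA fragment-length
    histograms into source-specific length signatures and per-sample mixing
    weights using non-negative matrix factorization with the generalized
    Kullback-Leibler loss. Estimates circulating tumor DNA burden from the
    tumor-signature weight, derives driver-variant-based ctDNA fractions,
    computes short/long fragment ratios, builds genome-binned chromatin-state
    length signatures, and classifies case versus control cohorts with a
    linear support-vector machine under repeated stratified cross-validation.
    Includes fragment-length extraction from paired-end alignments and a
    ground-truth synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
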
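Package: binpbs
Title: Probability of Being Signal for Binned ChIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bins a genome into fixed-width windows, counts aligned ChIP-seq
    reads per bin, rescales counts for mappability and copy number, fits a
    gamma background distribution to the low-count half of the data by a
    modified Cramer-von-Mises criterion, and assigns each bin a probability
    of being signal (PBS) in [0, 1]. Includes differential PBS between
    samples, category summaries, peak/annotation overlap tables, copy-number
    detection via Hartigan's dip test with ploidy-ratio rescaling, and a
    fully labelled synthetic-data generator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    GenomicAlignments,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
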
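# shared fixture builders; everything is generated in code at test time

toy_bins <- function(n = 10L, bin_size = 5000L, chrom = "chr1") {
  make_genome_bins(stats::setNames(n * bin_size, chrom), bin_size = bin_size)
}

# brute-force per-base interval intersection, the oracle for all overlap ops
brute_overlap_bp <- function(bin_start0, bin_end0, iv_start0, iv_end0) {
  total <- 0L
  for (i in seq_along(iv_start0)) {
    lo <- max(bin_start0, iv_start0[i])
    hi <- min(bin_end0, iv_end0[i])
    if (hi > lo) total <- total + (hi - lo)
  }
  total
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p-value
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

granges0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0))
}
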
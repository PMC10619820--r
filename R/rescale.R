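#' Fill per-bin mappability from a mappability track
#'
#' Per-bin mappability is the fraction of base positions in the bin where a
#' read of the given length aligns uniquely: the coverage-weighted mean of
#' the track over the bin span, with uncovered bases counted as 0. Bins with
#' no track data on their chromosome are left NA.
#'
#' @param bins GenomeBins
#' @param mappability a GRanges with a \code{score} in [0,1], or a
#'   bedGraph / 4-column BED / bigWig path
#' @param read_length read length in bp; published per-base tracks exist
#'   for 25, 36, 50, 75 and 100 bp reads (a warning is issued otherwise)
#' @param paired_end if TRUE the 100 bp track convention applies (paired
#'   reads have no single well-defined length), and \code{read_length} is
#'   recorded as 100
#' @return GenomeBins with the \code{mappability} column filled
#' @export
average_mappability <- function(bins, mappability, read_length = 100L,
                                paired_end = FALSE) {
  .check_bins(bins)
  if (isTRUE(paired_end)) read_length <- 100L
  if (!read_length %in% c(25L, 36L, 50L, 75L, 100L))
    warning("read_length ", read_length,
            " has no matching published mappability track (25/36/50/75/100)")
  gr <- if (methods::is(mappability, "GRanges")) mappability else
    .as_granges(mappability,
                format = if (grepl("\\.(bw|bigwig)$", mappability,
                                   ignore.case = TRUE)) NULL else "bedGraph")
  score <- as.numeric(S4Vectors::mcols(gr)$score)
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("mappability values must lie in [0, 1]")
  gr <- .reconcile_chrom_names(gr, bins)

  m <- rep(NA_real_, length(bins))
  ov <- GenomicRanges::findOverlaps(gr, bins, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(gr)[q], GenomicRanges::granges(bins)[s]))
    num <- rowsum(score[q] * ow, group = s)
    idx <- as.integer(rownames(num))
    m[idx] <- num[, 1] / GenomicRanges::width(bins)[idx]
  }
  S4Vectors::mcols(bins)$mappability <- m
  bins
}

#' Rescale counts by mappability
#'
#' Bins scoring below \code{min_mappability} (or with no mappability data)
#' are excluded (reason \code{"low_mappability"}) and their value set NA;
#' the remaining counts are divided by their mappability score, so a score
#' of exactly 1 leaves the value unchanged and rescaling never decreases a
#' count.
#'
#' @param counts BinTrack of raw counts
#' @param bins GenomeBins with mappability filled
#' @param min_mappability exclusion cutoff in (0, 1], default 0.5
#' @return list with elements \code{track} (rescaled BinTrack) and
#'   \code{bins} (updated GenomeBins)
#' @export
mappability_rescale <- function(counts, bins, min_mappability = 0.5) {
  .check_track(counts, bins)
  if (!is.numeric(min_mappability) || min_mappability <= 0 || min_mappability > 1)
    stop("min_mappability must lie in (0, 1]")
  m <- S4Vectors::mcols(bins)$mappability
  low <- is.na(m) | m < min_mappability
  newly <- low & !S4Vectors::mcols(bins)$excluded
  S4Vectors::mcols(bins)$excluded[newly] <- TRUE
  S4Vectors::mcols(bins)$reason[newly] <- "low_mappability"

  vals <- counts$values
  vals[low] <- NA_real_
  vals[!low] <- vals[!low] / m[!low]
  vals[S4Vectors::mcols(bins)$excluded] <- NA_real_
  track <- bin_track(vals, kind = "rescaled_counts", sample = counts$sample,
                     read_length = counts$read_length,
                     paired_end = counts$paired_end)
  list(track = track, bins = bins)
}

#' Rescale counts by per-bin ploidy ratios
#'
#' Divides each bin's count by its estimated fold-change-from-diploid, so
#' copy-number gains and losses no longer masquerade as enrichment or
#' depletion. Missing values stay missing.
#'
#' @param counts BinTrack
#' @param cnv a \code{CnvResult} (see \code{\link{detect_cnv}}) or a numeric
#'   vector of per-bin ratios
#' @return BinTrack of kind \code{rescaled_counts}
#' @export
cnv_rescale <- function(counts, cnv) {
  ratio <- if (inherits(cnv, "CnvResult")) cnv$ploidy_ratio$values else as.numeric(cnv)
  if (length(ratio) != length(counts$values))
    stop("ploidy ratio track is not aligned to the counts")
  if (any(ratio <= 0, na.rm = TRUE)) stop("ploidy ratios must be positive")
  vals <- counts$values / ratio
  bin_track(vals, kind = "rescaled_counts", sample = counts$sample,
            read_length = counts$read_length, paired_end = counts$paired_end)
}
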
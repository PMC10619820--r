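#' Hartigan's dip test of unimodality
#'
#' Computes the dip statistic — the smallest sup-distance between the
#' empirical CDF and any unimodal CDF — and a bootstrap p-value against
#' uniform(0,1) null samples of the same size (the classical least
#' favourable unimodal null, which makes the test conservative for
#' lighter-tailed unimodal data such as gamma counts).
#'
#' @param values numeric sample (length >= 4)
#' @param n_boot number of bootstrap null samples (>= 100)
#' @param seed optional integer seed for the bootstrap
#' @param null_dips optional precomputed vector of null dip statistics for
#'   samples of the same size, e.g. shared across equal-sized subsets
#' @return list with \code{statistic}, \code{p.value}, \code{n},
#'   \code{n_boot}
#' @export
dip_test <- function(values, n_boot = 1000L, seed = NULL, null_dips = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("dip test needs at least 4 values")
  d <- .dip_stat_cpp(as.numeric(values))
  if (is.null(null_dips)) {
    if (n_boot < 100L) stop("n_boot must be at least 100")
    if (!is.null(seed)) set.seed(seed)
    null_dips <- .dip_null_cpp(length(values), as.integer(n_boot))
  }
  p <- (1 + sum(null_dips >= d)) / (length(null_dips) + 1)
  list(statistic = d, p.value = p, n = length(values),
       n_boot = length(null_dips))
}

#' Dip statistic only
#' @param values numeric sample
#' @return the dip statistic
#' @export
dip_stat <- function(values) .dip_stat_cpp(as.numeric(values[!is.na(values)]))

#' Detect copy-number variation by subset multimodality
#'
#' Usable bins in genome order are split into \code{n_subsets} contiguous,
#' equal-count subsets that span chromosome boundaries (deliberately not
#' aligned to chromosomes, so whole-chromosome losses still create mixtures
#' within subsets), and each subset's count distribution is dip-tested. A
#' CNV is declared when any Bonferroni-adjusted p-value is significant.
#' Run this on an input-control track so that CNVs are not confused with
#' true enrichment.
#'
#' @param input_counts BinTrack of an input control (raw or rescaled counts)
#' @param bins GenomeBins (optional; used to restrict to usable bins)
#' @param n_subsets number of contiguous subsets (default 20)
#' @param alpha family-wise significance level (default 0.05; per-test
#'   level is \code{alpha / n_subsets})
#' @param n_boot bootstrap replicates per dip test
#' @param seed seed for the bootstrap null
#' @param null_dips optional precomputed null dip table (all subsets share
#'   one table since they have equal size)
#' @return a \code{CnvResult}: \code{subset_pvalues}, \code{dips},
#'   \code{detected}, and a \code{ploidy_ratio} BinTrack (all 1.0 until
#'   \code{\link{estimate_ploidy}} fills it)
#' @export
detect_cnv <- function(input_counts, bins = NULL, n_subsets = 20L,
                       alpha = 0.05, n_boot = 1000L, seed = 1L,
                       null_dips = NULL) {
  vals <- input_counts$values
  use <- !is.na(vals)
  if (!is.null(bins)) use <- use & usable_bins(bins)
  v <- vals[use]
  if (length(v) < 4L * n_subsets)
    stop("need at least ", 4L * n_subsets, " usable bins for ", n_subsets,
         " subsets")
  grp <- cut(seq_along(v), breaks = n_subsets, labels = FALSE)
  sizes <- tabulate(grp, n_subsets)

  if (length(unique(v)) == 1L) {
    warning("all counts identical; dip test degenerate, no CNV called")
    return(.cnv_result(rep(1, n_subsets), rep(0, n_subsets), FALSE,
                       length(vals), alpha, n_subsets))
  }
  if (is.null(null_dips)) {
    if (!is.null(seed)) set.seed(seed)
    null_dips <- .dip_null_cpp(as.integer(round(mean(sizes))),
                               as.integer(n_boot))
  }
  dips <- vapply(split(v, grp), .dip_stat_cpp, numeric(1))
  pvals <- vapply(dips, function(d)
    (1 + sum(null_dips >= d)) / (length(null_dips) + 1), numeric(1))
  detected <- any(pvals < alpha / n_subsets)
  .cnv_result(pvals, dips, detected, length(vals), alpha, n_subsets)
}

.cnv_result <- function(pvals, dips, detected, n_bins, alpha, n_subsets,
                        ratio = NULL) {
  structure(list(subset_pvalues = unname(pvals), dips = unname(dips),
                 detected = detected, alpha = alpha, n_subsets = n_subsets,
                 ploidy_ratio = bin_track(ratio %||% rep(1, n_bins),
                                          kind = "rescaled_counts")),
            class = "CnvResult")
}

#' @export
print.CnvResult <- function(x, ...) {
  cat(sprintf("CnvResult: detected=%s (min p=%.3g, per-test level %.3g)\n",
              x$detected, min(x$subset_pvalues), x$alpha / x$n_subsets))
  invisible(x)
}

#' Estimate per-bin ploidy ratios
#'
#' Given a detected CNV, segments the (median-smoothed) input-control
#' counts into contiguous runs, fits a normal mixture to segment medians
#' (model order 1..\code{max_states} by BIC), labels the component carrying
#' the largest number of bins as diploid, and returns each bin's
#' fold-change-from-diploid: the mean of its assigned component divided by
#' the diploid component mean.
#'
#' @param input_counts BinTrack of the input control
#' @param bins GenomeBins (optional)
#' @param cnv CnvResult from \code{\link{detect_cnv}} (must have
#'   \code{detected = TRUE})
#' @param max_states maximum number of copy states (default 6)
#' @param smooth_k running-median window in bins (odd, default 11)
#' @param jump_frac fraction of the global median treated as a segment
#'   boundary jump in the smoothed signal (default 0.2)
#' @return CnvResult with the \code{ploidy_ratio} track filled; if the
#'   mixture fit fails, \code{detected} is set FALSE with a warning
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_ploidy <- function(input_counts, bins = NULL, cnv,
                            max_states = 6L, smooth_k = 11L,
                            jump_frac = 0.2) {
  stopifnot(inherits(cnv, "CnvResult"))
  if (!cnv$detected) stop("estimate_ploidy requires detect_cnv detected = TRUE")
  vals <- input_counts$values
  use <- !is.na(vals)
  if (!is.null(bins)) use <- use & usable_bins(bins)
  v <- vals[use]

  sm <- stats::runmed(v, k = smooth_k, endrule = "median")
  jump <- abs(diff(sm)) > jump_frac * stats::median(sm)
  seg <- cumsum(c(TRUE, jump))          # contiguous-run segment ids
  # long runs are chunked so the mixture sees many segment medians and the
  # diploid ("most bins") rule is weighted by genome share, not run count
  chunk <- 500L
  off <- unlist(lapply(rle(seg)$lengths, function(l)
    rep(seq_len(ceiling(l / chunk)), each = chunk, length.out = l)),
    use.names = FALSE)
  seg <- cumsum(c(TRUE, diff(seg) != 0 | diff(off) != 0))
  seg_med <- tapply(v, seg, stats::median)
  seg_len <- tapply(v, seg, length)

  g_max <- min(max_states, length(seg_med))
  fit <- tryCatch(
    Mclust(as.numeric(seg_med), G = seq_len(g_max), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$classification)) {
    warning("mixture fit on segment medians failed; reverting to no-CNV")
    out <- .cnv_result(cnv$subset_pvalues, cnv$dips, FALSE, length(vals),
                       cnv$alpha, cnv$n_subsets)
    return(out)
  }
  cls <- fit$classification
  comp_mean <- fit$parameters$mean
  bins_per_comp <- tapply(as.numeric(seg_len), cls, sum)
  diploid <- as.integer(names(which.max(bins_per_comp)))
  ratio_by_seg <- unname(comp_mean[cls] / comp_mean[diploid])

  ratio <- rep(1, length(vals))
  ratio[use] <- ratio_by_seg[seg]
  .cnv_result(cnv$subset_pvalues, cnv$dips, TRUE, length(vals),
              cnv$alpha, cnv$n_subsets, ratio = ratio)
}

#' Export ploidy ratios as a bedGraph
#' @param cnv CnvResult with ratios filled
#' @param bins GenomeBins
#' @param path output path
#' @return the path, invisibly
#' @export
write_ploidy_ratios <- function(cnv, bins, path) {
  write_bin_track(cnv$ploidy_ratio, bins, path, format = "bedGraph")
}
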
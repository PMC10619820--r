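#' Per-bin probability of being signal
#'
#' For a bin with count x in a histogram cell with empirical density f(x)
#' and fitted background density f*(x):
#' \deqn{PBS(x) = (f(x) - \lambda f^*(x;\alpha,\beta)) / f(x)} when
#' \eqn{f(x) > \lambda f^*(x)}, and 0 otherwise — the fraction of bins at
#' that count level that the background cannot explain (1 minus a local
#' false-discovery rate). PBS is piecewise constant per histogram cell, so
#' identical counts always receive identical PBS. Counts beyond the grid
#' fall in the overflow cell (their number is reported via a message).
#'
#' @param counts BinTrack of rescaled counts (the same data
#'   \code{emp} and \code{fit} were built from)
#' @param emp EmpiricalDistribution
#' @param fit GammaBackgroundFit (must have converged)
#' @param bins optional GenomeBins; excluded bins get NA
#' @param isotonic if TRUE, the per-cell PBS curve is additionally forced
#'   non-decreasing in x by isotonic regression (off by default: the raw
#'   ratio can legitimately be non-monotone in sparse tails)
#' @return BinTrack of kind \code{pbs}
#' @export
compute_pbs <- function(counts, emp, fit, bins = NULL, isotonic = FALSE) {
  stopifnot(inherits(emp, "EmpiricalDistribution"),
            inherits(fit, "GammaBackgroundFit"))
  if (!fit$converged)
    warning("background fit did not converge; PBS values may be unreliable")
  v <- counts$values
  if (!is.null(bins)) {
    .check_track(counts, bins)
    v[!usable_bins(bins)] <- NA_real_
  }
  f <- emp$density
  # cell-averaged background density: exact gamma mass / cell width, which
  # stays meaningful in the tail and the wide overflow cell
  fstar <- .gamma_cell_mass(emp$breaks, fit$alpha, fit$beta) / emp$widths
  cell_pbs <- ifelse(f > 0, pmax(0, pmin(1, (f - fit$lam * fstar) / f)),
                     NA_real_)
  if (isotonic) {
    ok <- !is.na(cell_pbs)
    cell_pbs[ok] <- stats::isoreg(emp$grid[ok], cell_pbs[ok])$yf
  }
  ok <- !is.na(v)
  cell <- findInterval(v[ok], emp$breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  n_over <- sum(v[ok] > emp$breaks[length(emp$breaks)])
  if (n_over > 0)
    message(n_over, " bin(s) exceed the histogram range; assigned the ",
            "overflow cell's PBS")
  out <- rep(NA_real_, length(v))
  out[ok] <- cell_pbs[cell]
  if (anyNA(out[ok]))
    warning(sum(is.na(out[ok])), " bin(s) fell in empty histogram cells; ",
            "PBS set to NA")
  track <- bin_track(out, kind = "pbs", sample = counts$sample,
                     read_length = counts$read_length,
                     paired_end = counts$paired_end)
  attr(track, "isotonic") <- isotonic
  track
}

#' Differential PBS between two samples
#'
#' PBS values are universally normalised, so differential enrichment is
#' simple bin-wise subtraction \code{a - b}, yielding values in [-1, 1].
#' Bins missing in either track are missing in the result. Exactly
#' antisymmetric: \code{differential_pbs(a, b) == -differential_pbs(b, a)}.
#'
#' @param a,b BinTrack objects of kind \code{pbs} on the same scaffold
#' @return BinTrack of kind \code{diff_pbs}
#' @export
differential_pbs <- function(a, b) {
  stopifnot(inherits(a, "BinTrack"), inherits(b, "BinTrack"))
  if (a$kind != "pbs" || b$kind != "pbs") stop("both tracks must be PBS tracks")
  if (length(a$values) != length(b$values))
    stop("tracks are not on the same bin scaffold")
  bin_track(a$values - b$values, kind = "diff_pbs",
            sample = paste(a$sample, b$sample, sep = "-"))
}

#' Threshold a PBS or differential-PBS track
#'
#' Strict inequality, matching the convention "PBS > 0.9"; for differential
#' tracks, \code{absolute = TRUE} flags \code{|value| > cutoff} so that
#' both gains and losses count.
#'
#' @param track BinTrack of kind \code{pbs} or \code{diff_pbs}
#' @param cutoff threshold (default 0.9)
#' @param absolute compare absolute values (for diff tracks)
#' @return logical per bin (NA where the track is missing)
#' @export
threshold_pbs <- function(track, cutoff = 0.9, absolute = FALSE) {
  v <- track$values
  if (absolute) abs(v) > cutoff else v > cutoff
}

#' Summarise a PBS track into categories
#'
#' Cuts PBS values into half-open categories \code{[e_i, e_{i+1})} (the
#' last closed at 1). The defaults give low / moderate / high
#' (\code{edges = c(0.1, 0.9)}); \code{edges = seq(0.2, 0.8, by = 0.2)}
#' gives five 0.2-wide groups.
#'
#' @param track BinTrack of kind \code{pbs}
#' @param edges strictly increasing interior cut points inside (0, 1)
#' @return a \code{PbsCategories}: \code{breaks}, \code{labels},
#'   \code{counts}, \code{fractions} (over usable, non-missing bins)
#' @export
summarize_categories <- function(track, edges = c(0.1, 0.9)) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0) || any(edges >= 1))
    stop("edges must be strictly increasing and inside (0, 1)")
  v <- track$values
  v <- v[!is.na(v)]
  breaks <- c(0, edges, 1)
  cell <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(cell, nbins = length(breaks) - 1L)
  labels <- sprintf("[%.3g,%.3g%s", breaks[-length(breaks)], breaks[-1],
                    c(rep(")", length(breaks) - 2L), "]"))
  structure(list(breaks = breaks, labels = labels, counts = counts,
                 fractions = counts / sum(counts)),
            class = "PbsCategories")
}

#' @export
print.PbsCategories <- function(x, ...) {
  df <- data.frame(category = x$labels, bins = x$counts,
                   fraction = round(x$fractions, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' PBS matrix over a region
#'
#' Rows are samples, columns are the bins intersecting the region (any
#' overlap counts). Useful as a compact sample-by-position summary of
#' enrichment, e.g. for heatmap display.
#'
#' @param tracks list of PBS BinTracks on a shared scaffold
#' @param bins GenomeBins
#' @param region string \code{"chrom:start-end"} in 0-based half-open
#'   coordinates
#' @param path optional TSV output path (columns headed by bin coordinates)
#' @return numeric matrix (samples x bins)
#' @export
pbs_matrix <- function(tracks, bins, region, path = NULL) {
  if (inherits(tracks, "BinTrack")) tracks <- list(tracks)
  for (t in tracks) .check_track(t, bins)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must look like 'chrom:start-end'")
  gr <- GenomicRanges::GRanges(m[2], IRanges::IRanges(
    start = as.integer(m[3]) + 1L, end = as.integer(m[4])))
  if (!as.character(GenomeInfoDb::seqnames(gr)) %in%
        GenomeInfoDb::seqlevels(bins))
    stop("region chromosome '", m[2], "' is not on the bin scaffold")
  idx <- which(IRanges::overlapsAny(bins, gr, ignore.strand = TRUE))
  if (length(idx) == 0L) stop("region overlaps no bins")
  mat <- do.call(rbind, lapply(tracks, function(t) t$values[idx]))
  rownames(mat) <- vapply(seq_along(tracks), function(i) {
    s <- tracks[[i]]$sample
    if (is.na(s)) paste0("sample", i) else s
  }, character(1))
  colnames(mat) <- sprintf("%s:%d-%d",
                           as.character(GenomeInfoDb::seqnames(bins)[idx]),
                           GenomicRanges::start(bins)[idx] - 1L,
                           GenomicRanges::end(bins)[idx])
  if (!is.null(path))
    utils::write.table(mat, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  mat
}
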
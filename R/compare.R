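#' Annotate bins by interval overlap
#'
#' TRUE for every bin with at least \code{min_overlap_bp} base pairs of
#' overlap with any interval — e.g. "does this bin contain a peak".
#' Idempotent; merging adjacent intervals does not change the annotation.
#'
#' @param bins GenomeBins
#' @param intervals a GRanges or a BED / narrowPeak / broadPeak path (the
#'   first three columns are used)
#' @param min_overlap_bp minimum overlap in bp (default 1)
#' @return logical vector, one per bin
#' @export
annotate_bins <- function(bins, intervals, min_overlap_bp = 1L) {
  .check_bins(bins)
  gr <- .as_granges(intervals)
  gr <- .reconcile_chrom_names(gr, bins)
  IRanges::overlapsAny(bins, gr, minoverlap = min_overlap_bp,
                             ignore.strand = TRUE)
}

#' Cross-tabulate PBS categories against annotations
#'
#' Rows are PBS (or differential-PBS) categories, columns are annotation
#' states; with two annotations the columns are nested (annotation1 within
#' annotation2), matching stratified comparisons such as
#' inside-vs-outside a domain split by chromatin compartment.
#'
#' @param track BinTrack (pbs or diff_pbs)
#' @param edges interior category cut points (see
#'   \code{\link{summarize_categories}})
#' @param annotations a logical vector, or a (possibly named) list of one
#'   or two logical vectors aligned to the bins
#' @return an \code{OverlapTable} (a \code{table}) of bin counts
#' @export
overlap_table <- function(track, edges = c(0.1, 0.9), annotations) {
  if (is.logical(annotations)) annotations <- list(annotations)
  stopifnot(length(annotations) %in% 1:2)
  for (a in annotations)
    if (length(a) != length(track$values))
      stop("annotation length does not match the track")
  v <- track$values
  keep <- !is.na(v)
  lo <- if (track$kind == "diff_pbs") -1 else 0
  breaks <- c(lo, edges, 1)
  cell <- findInterval(v[keep], breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  labels <- sprintf("[%.3g,%.3g%s", breaks[-length(breaks)], breaks[-1],
                    c(rep(")", length(breaks) - 2L), "]"))
  cat_f <- factor(labels[cell], levels = labels)
  args <- c(list(category = cat_f),
            lapply(annotations, function(a) factor(a[keep],
                                                   levels = c(FALSE, TRUE))))
  if (is.null(names(annotations)) || any(names(annotations) == ""))
    names(args)[-1] <- paste0("annotation", seq_along(annotations))
  else names(args)[-1] <- names(annotations)
  tab <- do.call(table, args)
  class(tab) <- c("OverlapTable", class(tab))
  tab
}

#' Two-sided exact test on a 2x2 table
#'
#' Fisher's exact test with the odds ratio reported as the plain
#' cross-product ratio (ad)/(bc) rather than the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative integer bin counts
#' @return list with \code{odds_ratio} and \code{p.value}
#' @export
proportion_test <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the table is all zero")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p.value = ft$p.value)
}
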
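#' Specify a synthetic binned ChIP-seq dataset
#'
#' Defines a two-component count-generating model: a gamma background of
#' fraction \code{lam}, plus a signal component (gamma with mean
#' \code{signal_fold} times the background mean) occupying the remaining
#' bins either at random positions or in contiguous blocks. Optional CNV
#' segments multiply counts by an integer-ish copy ratio, and a fraction of
#' bins can be given reduced mappability (counts are multiplied by the
#' score, emulating lost multimapping reads).
#'
#' @param n_bins number of bins
#' @param alpha,beta background gamma shape and rate (defaults 3 and 0.1:
#'   mean 30 counts per bin, a typical moderately-sequenced ChIP)
#' @param lam background fraction in (0, 1]
#' @param signal_fold signal mean as a multiple of the background mean
#'   (default 6)
#' @param signal_shape gamma shape of the signal component (defaults to
#'   \code{alpha}, i.e. the background scaled up \code{signal_fold}-fold)
#' @param layout \code{"random"} scatters signal bins; \code{"blocks"}
#'   places them in \code{n_blocks} contiguous blocks (broad domains)
#' @param n_blocks number of signal blocks for the block layout
#' @param cnv_segments optional data frame with columns \code{start_bin},
#'   \code{end_bin} (1-based, inclusive) and \code{copy_ratio}
#' @param low_map_fraction fraction of bins given reduced mappability
#' @param map_score_range range the low-mappability scores are drawn from
#' @param bin_size bin width used when materialising a genome scaffold
#' @param seed integer seed; all randomness flows from it
#' @return a \code{SimulationSpec}
#' @export
simulation_spec <- function(n_bins, alpha = 3, beta = 0.1, lam = 0.85,
                            signal_fold = 6, signal_shape = NULL,
                            layout = c("random", "blocks"), n_blocks = 20L,
                            cnv_segments = NULL, low_map_fraction = 0,
                            map_score_range = c(0.2, 0.95),
                            bin_size = 5000L, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_bins >= 1, alpha > 0, beta > 0, lam > 0, lam <= 1,
            signal_fold > 0, low_map_fraction >= 0, low_map_fraction < 1)
  if (!is.null(cnv_segments)) {
    stopifnot(all(c("start_bin", "end_bin", "copy_ratio") %in%
                    names(cnv_segments)),
              all(cnv_segments$copy_ratio > 0),
              all(cnv_segments$start_bin >= 1),
              all(cnv_segments$end_bin <= n_bins),
              all(cnv_segments$start_bin <= cnv_segments$end_bin))
  }
  structure(list(n_bins = as.integer(n_bins), alpha = alpha, beta = beta,
                 lam = lam, signal_fold = signal_fold,
                 signal_shape = signal_shape %||% alpha, layout = layout,
                 n_blocks = as.integer(n_blocks),
                 cnv_segments = cnv_segments,
                 low_map_fraction = low_map_fraction,
                 map_score_range = map_score_range,
                 bin_size = as.integer(bin_size), seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate labelled bin counts
#'
#' Draws counts from the two-component model of a \code{SimulationSpec},
#' applies CNV copy ratios and mappability attenuation, and returns
#' everything an oracle test needs: the truth labels and the closed-form
#' posterior \eqn{P(signal | x) = 1 - \lambda f^*(x) / f_{mix}(x)} of the
#' generating mixture (before CNV/mappability distortion).
#'
#' @param spec a \code{SimulationSpec}
#' @return list with \code{bins} (GenomeBins on one synthetic chromosome),
#'   \code{track} (raw-count BinTrack), \code{labels} (logical, TRUE =
#'   signal), \code{posterior} (function of count x), \code{mappability}
#'   (per-bin scores), \code{cnv_ratio} (true per-bin copy ratio),
#'   \code{spec}
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$n_bins
  n_sig <- round((1 - spec$lam) * n)
  labels <- rep(FALSE, n)
  if (n_sig > 0) {
    if (spec$layout == "random") {
      labels[sample.int(n, n_sig)] <- TRUE
    } else {
      labels <- .place_blocks(n, n_sig, spec$n_blocks)
    }
  }
  mean_sig <- spec$signal_fold * spec$alpha / spec$beta
  rate_sig <- spec$signal_shape / mean_sig
  counts <- numeric(n)
  counts[!labels] <- stats::rgamma(sum(!labels), shape = spec$alpha,
                                   rate = spec$beta)
  counts[labels] <- stats::rgamma(sum(labels), shape = spec$signal_shape,
                                  rate = rate_sig)

  cnv_ratio <- rep(1, n)
  if (!is.null(spec$cnv_segments)) {
    for (i in seq_len(nrow(spec$cnv_segments))) {
      s <- spec$cnv_segments[i, ]
      cnv_ratio[s$start_bin:s$end_bin] <- s$copy_ratio
    }
    counts <- counts * cnv_ratio
  }

  mappability <- rep(1, n)
  if (spec$low_map_fraction > 0) {
    k <- round(spec$low_map_fraction * n)
    idx <- sample.int(n, k)
    mappability[idx] <- stats::runif(k, spec$map_score_range[1],
                                     spec$map_score_range[2])
    counts <- counts * mappability
  }

  lam <- spec$lam; a <- spec$alpha; b <- spec$beta
  as_ <- spec$signal_shape; bs_ <- rate_sig
  posterior <- function(x) {
    fb <- stats::dgamma(x, shape = a, rate = b)
    fs <- stats::dgamma(x, shape = as_, rate = bs_)
    denom <- lam * fb + (1 - lam) * fs
    ifelse(denom > 0, (1 - lam) * fs / denom, 0)
  }

  # split the synthetic scaffold over ~250 Mb chromosomes so coordinates
  # stay within 32-bit range at any n_bins
  per_chrom <- 50000L
  k <- ceiling(n / per_chrom)
  sizes <- rep(per_chrom, k)
  sizes[k] <- n - per_chrom * (k - 1L)
  bins <- make_genome_bins(
    stats::setNames(as.numeric(sizes) * spec$bin_size,
                    paste0("chrS", seq_len(k))),
    bin_size = spec$bin_size)
  list(bins = bins,
       track = bin_track(counts, kind = "raw_counts", sample = "sim"),
       labels = labels, posterior = posterior, mappability = mappability,
       cnv_ratio = cnv_ratio, spec = spec)
}

# n_sig signal bins in n_blocks contiguous blocks, one per genome stratum
.place_blocks <- function(n, n_sig, n_blocks) {
  n_blocks <- max(1L, min(n_blocks, n_sig))
  len <- floor(n_sig / n_blocks)
  extra <- n_sig - len * n_blocks
  strata <- floor(seq(0, n, length.out = n_blocks + 1L))
  labels <- rep(FALSE, n)
  for (i in seq_len(n_blocks)) {
    bl <- len + (i <= extra)
    lo <- strata[i] + 1L
    hi <- strata[i + 1L]
    if (bl >= hi - lo + 1L) start <- lo
    else start <- lo + sample.int(hi - lo + 1L - bl, 1L) - 1L
    labels[start:(start + bl - 1L)] <- TRUE
  }
  labels
}

#' Simulate a broad histone mark
#'
#' Contiguous blocks covering \code{block_fraction} of the genome get
#' counts whose mean is only modestly elevated
#' (\code{enrichment_factor}-fold, typically 1.5-3x, same gamma shape).
#' Because the block and background distributions overlap heavily, the
#' expected outcome is intermediate PBS across the blocks rather than a
#' bimodal PBS histogram — the hallmark of broad repressive marks. With
#' \code{enrichment_factor = 1} the blocks are statistically
#' indistinguishable from background.
#'
#' @param spec a \code{SimulationSpec} providing the background and seed
#' @param block_fraction fraction of bins inside blocks, in (0, 1)
#' @param enrichment_factor fold elevation of the block mean
#' @return as \code{\link{simulate_counts}}
#' @export
simulate_broad_mark <- function(spec, block_fraction = 0.3,
                                enrichment_factor = 2) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (block_fraction <= 0 || block_fraction >= 1)
    stop("block_fraction must lie in (0, 1)")
  spec2 <- simulation_spec(
    n_bins = spec$n_bins, alpha = spec$alpha, beta = spec$beta,
    lam = 1 - block_fraction, signal_fold = enrichment_factor,
    signal_shape = spec$alpha, layout = "blocks", n_blocks = spec$n_blocks,
    cnv_segments = spec$cnv_segments,
    low_map_fraction = spec$low_map_fraction,
    map_score_range = spec$map_score_range, bin_size = spec$bin_size,
    seed = spec$seed)
  simulate_counts(spec2)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits \code{chrom.sizes}, \code{counts.bedGraph},
#' \code{mappability.bedGraph}, \code{truth.bed} (signal bins) and
#' \code{spec.json}; everything round-trips through the package's readers.
#'
#' @param sim output of \code{\link{simulate_counts}} or
#'   \code{\link{simulate_broad_mark}}
#' @param dir output directory (created if needed)
#' @return named character vector of the file paths, invisibly
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- sim$bins
  paths <- c(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    counts = file.path(dir, "counts.bedGraph"),
    mappability = file.path(dir, "mappability.bedGraph"),
    truth = file.path(dir, "truth.bed"),
    spec = file.path(dir, "spec.json"))
  utils::write.table(
    data.frame(chrom = GenomeInfoDb::seqlevels(bins),
               length = unname(GenomeInfoDb::seqlengths(bins))),
    paths["chrom_sizes"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bin_track(sim$track, bins, paths["counts"], format = "bedGraph")
  write_bin_track(bin_track(sim$mappability, kind = "rescaled_counts"),
                  bins, paths["mappability"], format = "bedGraph")
  sig <- GenomicRanges::granges(bins)[sim$labels]
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(sig)),
                   start = GenomicRanges::start(sig) - 1L,
                   end = GenomicRanges::end(sig))
  utils::write.table(df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sp <- sim$spec
  sp$cnv_segments <- if (is.null(sp$cnv_segments)) NULL else
    as.data.frame(sp$cnv_segments)
  jsonlite::write_json(unclass(sp), paths["spec"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
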
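#' Build the genome-wide bin scaffold
#'
#' Divides each chromosome into non-overlapping fixed-width windows. Full
#' windows start at position 0; the trailing partial window of each
#' chromosome is emitted but flagged excluded (reason \code{"partial_bin"})
#' so bin indices remain reconstructible from coordinates.
#'
#' @param chrom_sizes chromosome lengths: a named numeric vector, a
#'   two-column data frame (name, length), or the path to a two-column
#'   \code{chrom.sizes} TSV.
#' @param bin_size window width in base pairs. The default 5000 matches the
#'   resolution at which a gamma background describes bin counts well;
#'   widths below 3000 trigger a warning because counts become too discrete
#'   for the continuous background model.
#' @return A \code{GRanges} ("GenomeBins") with metadata column
#'   \code{mappability} (NA until filled), \code{copy_ratio} (1 = diploid),
#'   \code{excluded} and \code{reason}, and \code{metadata()$bin_size}.
#' @export
make_genome_bins <- function(chrom_sizes, bin_size = 5000L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("bin_size must be a positive integer")
  if (bin_size < 3000L)
    warning("bin_size < 3000 bp: bin counts become discrete and the gamma ",
            "background model may need adaptation")
  sizes <- .as_chrom_sizes(chrom_sizes)
  if (length(sizes) == 0L) stop("chrom_sizes is empty")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) stop("chromosome lengths must be positive")

  starts <- lapply(sizes, function(len) seq(1, len, by = bin_size))
  ends <- mapply(function(st, len) pmin(st + bin_size - 1, len),
                 starts, sizes, SIMPLIFY = FALSE)
  bins <- GenomicRanges::GRanges(
    seqnames = rep(names(sizes), lengths(starts)),
    ranges = IRanges::IRanges(start = unlist(starts, use.names = FALSE),
                              end = unlist(ends, use.names = FALSE)),
    seqinfo = GenomeInfoDb::Seqinfo(names(sizes), round(sizes)))
  partial <- GenomicRanges::width(bins) < bin_size
  S4Vectors::mcols(bins)$mappability <- NA_real_
  S4Vectors::mcols(bins)$copy_ratio <- 1.0
  S4Vectors::mcols(bins)$excluded <- partial
  S4Vectors::mcols(bins)$reason <- ifelse(partial, "partial_bin", NA_character_)
  S4Vectors::metadata(bins)$bin_size <- bin_size
  bins
}

.as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L && file.exists(chrom_sizes)) {
    tab <- utils::read.table(chrom_sizes, header = FALSE, sep = "\t",
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    chrom_sizes <- tab
  }
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    sizes <- chrom_sizes
  } else {
    stop("chrom_sizes must be a named vector, 2-column data frame, or chrom.sizes path")
  }
  sizes
}

#' Number of usable (non-excluded) bins
#' @param bins a GenomeBins object
#' @return logical vector, TRUE where the bin is usable
#' @export
usable_bins <- function(bins) !S4Vectors::mcols(bins)$excluded

.check_bins <- function(bins) {
  stopifnot(methods::is(bins, "GRanges"),
            all(c("mappability", "copy_ratio", "excluded", "reason") %in%
                  names(S4Vectors::mcols(bins))))
  invisible(bins)
}

#' Construct a per-bin value track
#'
#' A BinTrack is one value (possibly NA) per bin of an associated
#' GenomeBins scaffold, tagged with what the values are.
#'
#' @param values numeric vector, one per bin
#' @param kind one of \code{"raw_counts"}, \code{"rescaled_counts"},
#'   \code{"pbs"}, \code{"diff_pbs"}
#' @param sample sample label
#' @param read_length read length in bp (metadata)
#' @param paired_end logical (metadata)
#' @return an object of class \code{BinTrack}
#' @export
bin_track <- function(values, kind = c("raw_counts", "rescaled_counts", "pbs", "diff_pbs"),
                      sample = NA_character_, read_length = NA_integer_,
                      paired_end = NA) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (kind == "pbs" && any(values[ok] < 0 | values[ok] > 1))
    stop("pbs values must lie in [0, 1]")
  if (kind == "diff_pbs" && any(values[ok] < -1 | values[ok] > 1))
    stop("diff_pbs values must lie in [-1, 1]")
  if (kind %in% c("raw_counts", "rescaled_counts") && any(values[ok] < 0))
    stop("count values must be non-negative")
  structure(list(values = values, kind = kind, sample = sample,
                 read_length = read_length, paired_end = paired_end),
            class = "BinTrack")
}

#' @export
print.BinTrack <- function(x, ...) {
  cat(sprintf("BinTrack<%s> %d bins (%d missing)%s\n", x$kind, length(x$values),
              sum(is.na(x$values)),
              if (!is.na(x$sample)) paste0(" sample=", x$sample) else ""))
  invisible(x)
}

#' @export
length.BinTrack <- function(x) length(x$values)

.check_track <- function(track, bins = NULL) {
  stopifnot(inherits(track, "BinTrack"))
  if (!is.null(bins) && length(track$values) != length(bins))
    stop("BinTrack length (", length(track$values),
         ") does not match GenomeBins (", length(bins), ")")
  invisible(track)
}

#' Count aligned reads per bin
#'
#' Each kept read contributes \code{overlap_bp / read_length} to every bin
#' it overlaps, so a boundary read splits its unit weight across bins and
#' total counted weight equals the number of kept reads. Reads with
#' MAPQ below \code{mapq_min}, and unmapped / secondary / duplicate-flagged
#' records, contribute nothing.
#'
#' @param alignments path to a coordinate-sorted SAM/BAM file, a
#'   \code{GRanges} of reads with a \code{mapq} metadata column, or a data
#'   frame with columns \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{mapq}.
#' @param bins GenomeBins scaffold
#' @param mapq_min minimum MAPQ to keep a read (default 1, i.e. MAPQ < 1
#'   multimappers are dropped)
#' @return \code{BinTrack} of kind \code{raw_counts}
#' @export
count_reads <- function(alignments, bins, mapq_min = 1L) {
  .check_bins(bins)
  reads <- .as_read_granges(alignments)
  mapq <- S4Vectors::mcols(reads)$mapq
  mapq[is.na(mapq)] <- 0L
  reads <- reads[mapq >= mapq_min]

  reads <- .reconcile_chrom_names(reads, bins)
  known <- as.character(GenomeInfoDb::seqnames(reads)) %in%
    GenomeInfoDb::seqlevels(bins)
  if (any(!known)) {
    warning(sum(!known), " read(s) on chromosomes absent from the bin ",
            "scaffold were skipped")
    reads <- reads[known]
  }

  vals <- numeric(length(bins))
  if (length(reads)) {
    ov <- GenomicRanges::findOverlaps(reads, bins, ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      ovw <- GenomicRanges::width(GenomicRanges::pintersect(
        GenomicRanges::granges(reads)[q], GenomicRanges::granges(bins)[s]))
      w <- ovw / GenomicRanges::width(reads)[q]
      agg <- rowsum(w, group = s)
      vals[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  bin_track(vals, kind = "raw_counts")
}

.as_read_granges <- function(alignments) {
  if (methods::is(alignments, "GRanges")) {
    if (is.null(S4Vectors::mcols(alignments)$mapq))
      stop("read GRanges must carry a 'mapq' metadata column")
    return(alignments)
  }
  if (is.data.frame(alignments)) {
    if (nrow(alignments) == 0L)
      return(GenomicRanges::GRanges(mapq = integer(0)))
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(alignments$chrom),
      ranges = IRanges::IRanges(start = alignments$start + 1L,
                                end = alignments$end))
    S4Vectors::mcols(gr)$mapq <- alignments$mapq
    return(gr)
  }
  if (is.character(alignments) && length(alignments) == 1L) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading SAM/BAM requires the Rsamtools package")
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = TRUE)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
    ga <- GenomicAlignments::readGAlignments(path, param = param)
    gr <- GenomicRanges::granges(ga)
    S4Vectors::mcols(gr)$mapq <- S4Vectors::mcols(ga)$mapq
    return(gr)
  }
  stop("unsupported alignments input")
}

.reconcile_chrom_names <- function(gr, bins) {
  got <- GenomeInfoDb::seqlevels(gr)
  want <- GenomeInfoDb::seqlevels(bins)
  if (length(intersect(got, want)) > 0L || length(got) == 0L) return(gr)
  stripped <- sub("^chr", "", got)
  prefixed <- paste0("chr", got)
  if (length(intersect(stripped, want)) > 0L) {
    warning("stripping 'chr' prefix to reconcile chromosome names")
    GenomeInfoDb::seqlevels(gr) <- stripped
  } else if (length(intersect(prefixed, want)) > 0L) {
    warning("adding 'chr' prefix to reconcile chromosome names")
    GenomeInfoDb::seqlevels(gr) <- prefixed
  }
  gr
}

#' Exclude bins overlapping a blacklist
#'
#' Any bin with at least one base pair of overlap with a blacklist interval
#' is flagged excluded with reason \code{"blacklist"}; existing exclusion
#' reasons are preserved. Idempotent and order-independent.
#'
#' @param bins GenomeBins
#' @param blacklist a \code{GRanges} or the path to a BED file (0-based
#'   half-open)
#' @return the updated GenomeBins
#' @export
apply_blacklist <- function(bins, blacklist) {
  .check_bins(bins)
  bl <- .as_granges(blacklist)
  if (length(bl) == 0L) return(bins)
  bl <- .reconcile_chrom_names(bl, bins)
  hit <- IRanges::overlapsAny(bins, bl, ignore.strand = TRUE)
  newly <- hit & !S4Vectors::mcols(bins)$excluded
  S4Vectors::mcols(bins)$excluded[newly] <- TRUE
  S4Vectors::mcols(bins)$reason[newly] <- "blacklist"
  bins
}

.as_granges <- function(x, format = NULL) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (is.null(format)) {
      format <- if (grepl("\\.(bw|bigwig)$", x, ignore.case = TRUE)) "bigWig"
      else if (grepl("\\.(bedgraph|bdg)$", x, ignore.case = TRUE)) "bedGraph"
      else if (grepl("\\.narrowpeak$", x, ignore.case = TRUE)) "narrowPeak"
      else if (grepl("\\.broadpeak$", x, ignore.case = TRUE)) "broadPeak"
      else "BED"
    }
    gr <- switch(format,
      narrowPeak = rtracklayer::import(x, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")),
      broadPeak = rtracklayer::import(x, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric")),
      rtracklayer::import(x, format = format))
    return(gr)
  }
  stop("expected a GRanges or a file path")
}

#' Read per-bin values from a bedGraph or bigWig file
#'
#' When the file's intervals coincide exactly with the bins, values are
#' taken directly. Otherwise the file is treated as a coverage track and
#' each bin gets its coverage-weighted mean, multiplied by
#' \code{bin_size / read_length} when \code{read_length} is given (which
#' converts mean per-base coverage into a read-count equivalent).
#'
#' @param path bedGraph or bigWig file
#' @param bins GenomeBins
#' @param read_length optional read length for the coverage conversion
#' @param kind the kind of BinTrack to return (default \code{raw_counts})
#' @return a \code{BinTrack}; bins without data are NA
#' @export
read_bin_values <- function(path, bins, read_length = NULL,
                            kind = "raw_counts") {
  .check_bins(bins)
  gr <- .as_granges(path)
  gr <- .reconcile_chrom_names(gr, bins)
  score <- as.numeric(S4Vectors::mcols(gr)$score)
  vals <- rep(NA_real_, length(bins))

  eq <- GenomicRanges::findOverlaps(bins, gr, type = "equal",
                                    ignore.strand = TRUE)
  if (length(eq) == length(gr) && length(eq) <= length(bins) &&
      !anyDuplicated(S4Vectors::queryHits(eq))) {
    vals[S4Vectors::queryHits(eq)] <- score[S4Vectors::subjectHits(eq)]
    return(bin_track(vals, kind = kind,
                     read_length = read_length %||% NA_integer_))
  }

  ov <- GenomicRanges::findOverlaps(gr, bins, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(gr)[q], GenomicRanges::granges(bins)[s]))
    num <- rowsum(score[q] * ow, group = s)
    cov <- rowsum(as.numeric(ow), group = s)
    idx <- as.integer(rownames(num))
    m <- num[, 1] / GenomicRanges::width(bins)[idx]
    if (!is.null(read_length))
      m <- m * unname(S4Vectors::metadata(bins)$bin_size) / read_length
    vals[idx] <- m
  }
  bin_track(vals, kind = kind, read_length = read_length %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BinTrack to disk
#'
#' \code{bedGraph} writes a sorted 4-column bedGraph (0-based half-open) of
#' all usable, non-missing bins. \code{bed_threshold} writes a BED3
#' annotation of bins whose value is strictly greater than
#' \code{threshold} — e.g. PBS > 0.9 domains for downstream heritability
#' partitioning.
#'
#' @param track BinTrack
#' @param bins GenomeBins
#' @param path output file
#' @param format \code{"bedGraph"} or \code{"bed_threshold"}
#' @param threshold cutoff for \code{bed_threshold} (strict \code{>})
#' @param track_line optional character scalar written as a leading track
#'   line (provenance)
#' @return the path, invisibly
#' @export
write_bin_track <- function(track, bins, path,
                            format = c("bedGraph", "bed_threshold"),
                            threshold = 0.9, track_line = NULL) {
  format <- match.arg(format)
  .check_track(track, bins)
  keep <- usable_bins(bins) & !is.na(track$values)
  gr <- GenomicRanges::granges(bins)[keep]
  S4Vectors::mcols(gr)$score <- track$values[keep]
  gr <- GenomicRanges::sort(gr)
  if (format == "bed_threshold") {
    gr <- gr[S4Vectors::mcols(gr)$score > threshold]
    S4Vectors::mcols(gr)$score <- NULL
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
  } else {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     score = format(S4Vectors::mcols(gr)$score, digits = 10,
                                    scientific = FALSE, trim = TRUE))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
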
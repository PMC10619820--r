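#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the method's standard
#' defaults: 5 kB bins, background fitted below the median
#' (\code{theta_quantile} 0.5), mappability cutoff 0.5, 20 CNV subsets,
#' 1000 histogram cells, PBS threshold 0.9.
#'
#' @param counts path to a counts bedGraph, or a BinTrack (with
#'   \code{bins}); alternatively \code{alignments} may name a SAM/BAM file
#' @param chrom_sizes chrom.sizes path / named vector (required when
#'   \code{bins} is not given)
#' @param bins optional prebuilt GenomeBins
#' @param alignments optional SAM/BAM path (used when \code{counts} is NULL)
#' @param input_counts optional input-control counts (bedGraph path or
#'   BinTrack); enables the CNV branch
#' @param blacklist optional BED path / GRanges
#' @param mappability optional mappability track path / GRanges
#' @param out_dir output directory
#' @param bin_size,theta_quantile,min_mappability,n_subsets,n_grid,
#'   pbs_threshold,mapq_min,read_length,paired_end,n_boot method parameters
#' @param seed seed used for the CNV bootstrap
#' @param force emit PBS even when the background fit did not converge
#' @return a \code{RunConfig}
#' @export
run_config <- function(counts = NULL, chrom_sizes = NULL, bins = NULL,
                       alignments = NULL, input_counts = NULL,
                       blacklist = NULL, mappability = NULL,
                       out_dir = ".", bin_size = 5000L,
                       theta_quantile = 0.5, min_mappability = 0.5,
                       n_subsets = 20L, n_grid = 1000L,
                       pbs_threshold = 0.9, mapq_min = 1L,
                       read_length = 100L, paired_end = FALSE,
                       n_boot = 1000L, seed = 1L, force = FALSE) {
  structure(list(counts = counts, chrom_sizes = chrom_sizes, bins = bins,
                 alignments = alignments, input_counts = input_counts,
                 blacklist = blacklist, mappability = mappability,
                 out_dir = out_dir, bin_size = bin_size,
                 theta_quantile = theta_quantile,
                 min_mappability = min_mappability, n_subsets = n_subsets,
                 n_grid = n_grid, pbs_threshold = pbs_threshold,
                 mapq_min = mapq_min, read_length = read_length,
                 paired_end = paired_end, n_boot = n_boot, seed = seed,
                 force = force),
            class = "RunConfig")
}

# small deterministic FNV-1a hash for provenance lines
.config_hash <- function(config) {
  # method parameters only: file locations must not change the hash
  paths <- c("counts", "chrom_sizes", "bins", "alignments", "input_counts",
             "blacklist", "mappability", "out_dir")
  cfg <- unclass(config)[setdiff(names(config), paths)]
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 4, cfg)
  s <- paste(names(scalars), vapply(scalars, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full PBS pipeline
#'
#' Stages, in order: bin scaffold, read counting (or count import),
#' blacklist exclusion, mappability rescaling, CNV detection on the input
#' control (the costly ploidy estimation is skipped when no CNV is
#' detected), CNV rescaling, gamma background fit, PBS. Each stage logs one
#' structured line; every output file carries a provenance track line with
#' the package version, a config hash, and the seed. A non-converged
#' background fit blocks PBS emission unless \code{force = TRUE}.
#'
#' @param config a \code{RunConfig}
#' @return list with \code{bins}, \code{rescaled} (BinTrack), \code{fit},
#'   \code{emp}, \code{pbs} (BinTrack), \code{cnv} (CnvResult or NULL),
#'   \code{paths} of written files, \code{log} (character vector)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    line <- sprintf("[binpbs %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    log <<- c(log, line)
  }
  prov <- sprintf(
    'track type=bedGraph description="binpbs v%s cfg=%s seed=%d"',
    as.character(utils::packageVersion("binpbs")), .config_hash(config),
    config$seed)

  bins <- config$bins
  if (is.null(bins)) {
    if (is.null(config$chrom_sizes))
      stop("stage bin: either bins or chrom_sizes must be provided")
    bins <- make_genome_bins(config$chrom_sizes, config$bin_size)
  }
  say("bin: %d bins (%d usable), bin_size=%d", length(bins),
      sum(usable_bins(bins)), S4Vectors::metadata(bins)$bin_size)

  counts <- config$counts
  if (is.null(counts) && !is.null(config$alignments)) {
    counts <- count_reads(config$alignments, bins,
                          mapq_min = config$mapq_min)
    say("count: %.1f total read weight", sum(counts$values, na.rm = TRUE))
  } else if (is.character(counts)) {
    counts <- read_bin_values(counts, bins)
    say("count: imported %d bin values", sum(!is.na(counts$values)))
  }
  if (is.null(counts)) stop("stage count: no counts or alignments provided")
  .check_track(counts, bins)

  if (!is.null(config$blacklist)) {
    bins <- apply_blacklist(bins, config$blacklist)
    say("blacklist: %d bins excluded",
        sum(S4Vectors::mcols(bins)$reason == "blacklist", na.rm = TRUE))
  }

  if (!is.null(config$mappability)) {
    bins <- average_mappability(bins, config$mappability,
                                read_length = config$read_length,
                                paired_end = config$paired_end)
    mr <- mappability_rescale(counts, bins,
                              min_mappability = config$min_mappability)
    counts <- mr$track
    bins <- mr$bins
    say("mappability: %d bins excluded below %.2f",
        sum(S4Vectors::mcols(bins)$reason == "low_mappability",
            na.rm = TRUE), config$min_mappability)
  } else {
    vals <- counts$values
    vals[!usable_bins(bins)] <- NA_real_
    counts <- bin_track(vals, kind = "rescaled_counts",
                        sample = counts$sample)
  }

  cnv <- NULL
  if (!is.null(config$input_counts)) {
    input <- config$input_counts
    if (is.character(input)) input <- read_bin_values(input, bins)
    cnv <- detect_cnv(input, bins, n_subsets = config$n_subsets,
                      n_boot = config$n_boot, seed = config$seed)
    if (cnv$detected) {
      say("cnv: detected (min p=%.3g); estimating ploidy",
          min(cnv$subset_pvalues))
      cnv <- estimate_ploidy(input, bins, cnv)
      counts <- cnv_rescale(counts, cnv)
      say("cnv: rescaled by per-bin ploidy ratios")
    } else {
      say("cnv: none detected (min p=%.3g); ploidy estimation skipped",
          min(cnv$subset_pvalues))
    }
  }

  emp <- empirical_distribution(counts, n_grid = config$n_grid)
  fit <- fit_background(counts, theta_quantile = config$theta_quantile,
                        n_grid = config$n_grid, emp = emp)
  say("fit: alpha=%.4g beta=%.4g lambda=%.4g theta=%.4g omega2=%.3g q=%.4g",
      fit$alpha, fit$beta, fit$lam, fit$theta, fit$omega2, fit$q)
  if (!fit$converged && !config$force)
    stop("stage fit: background fit did not converge; rerun with force=TRUE ",
         "to emit PBS anyway")

  pbs <- compute_pbs(counts, emp, fit, bins = bins)
  say("pbs: %d bins scored, %d above %.2f", sum(!is.na(pbs$values)),
      sum(pbs$values > config$pbs_threshold, na.rm = TRUE),
      config$pbs_threshold)

  paths <- c(rescaled = file.path(config$out_dir, "rescaled.bedGraph"),
             fit = file.path(config$out_dir, "fit.tsv"),
             pbs = file.path(config$out_dir, "pbs.bedGraph"),
             log = file.path(config$out_dir, "binpbs.log"))
  write_bin_track(counts, bins, paths["rescaled"], format = "bedGraph",
                  track_line = prov)
  write_fit(fit, paths["fit"])
  write_bin_track(pbs, bins, paths["pbs"], format = "bedGraph",
                  track_line = prov)
  if (!is.null(cnv)) {
    paths["ploidy"] <- file.path(config$out_dir, "ploidy.bedGraph")
    write_bin_track(cnv$ploidy_ratio, bins, paths["ploidy"],
                    format = "bedGraph", track_line = prov)
  }
  writeLines(log, paths["log"])
  list(bins = bins, rescaled = counts, fit = fit, emp = emp, pbs = pbs,
       cnv = cnv, paths = paths, log = log)
}
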
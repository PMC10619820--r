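test_that("bin scaffold construction follows floor division with flagged partials", {
  b <- make_genome_bins(c(chr1 = 10000), bin_size = 5000)
  expect_length(b, 2L)
  expect_true(all(usable_bins(b)))
  expect_equal(GenomicRanges::start(b) - 1L, c(0L, 5000L))
  expect_equal(GenomicRanges::end(b), c(5000L, 10000L))

  b2 <- make_genome_bins(c(chr1 = 4999), bin_size = 5000)
  expect_length(b2, 1L)
  expect_false(any(usable_bins(b2)))
  expect_equal(S4Vectors::mcols(b2)$reason, "partial_bin")

  # floor-division oracle on a chromosome-sized input
  len <- 46709983
  b3 <- make_genome_bins(c(chr21 = len), bin_size = 5000)
  expect_equal(sum(usable_bins(b3)), len %/% 5000)   # 9341
  expect_equal(sum(GenomicRanges::width(b3)[usable_bins(b3)]),
               (len %/% 5000) * 5000)

  expect_error(make_genome_bins(c(chr1 = 0)), "positive")
  expect_error(make_genome_bins(numeric(0)), "empty|named")
  expect_warning(make_genome_bins(c(chr1 = 10000), bin_size = 2000),
                 "3000")
})

test_that("scaffold is deterministic and multi-chromosome aware", {
  sizes <- c(chrA = 23000, chrB = 11000)
  b1 <- make_genome_bins(sizes)
  b2 <- make_genome_bins(sizes)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_equal(sum(usable_bins(b1)), 4L + 2L)
  expect_equal(sum(!usable_bins(b1)), 2L)
})

test_that("read counting uses fractional overlap weights and MAPQ filtering", {
  bins <- toy_bins(2)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mapq = integer(0))
  expect_equal(count_reads(empty, bins)$values, c(0, 0))

  # one 100 bp read straddling the bin boundary splits its weight
  r <- data.frame(chrom = "chr1", start = 4950, end = 5050, mapq = 30)
  expect_equal(count_reads(r, bins)$values, c(0.5, 0.5))

  # MAPQ < 1 reads contribute nothing
  r2 <- data.frame(chrom = "chr1",
                   start = c(100, 300, 500, 700),
                   end = c(200, 400, 600, 800),
                   mapq = c(30, 30, 30, 0))
  expect_equal(count_reads(r2, bins)$values, c(3, 0))
})

test_that("counting conserves total read weight", {
  set.seed(42)
  bins <- toy_bins(20)
  n <- 500
  st <- sample.int(20 * 5000 - 120, n)
  r <- data.frame(chrom = "chr1", start = st, end = st + 100,
                  mapq = sample(c(0, 10, 30), n, replace = TRUE))
  tr <- count_reads(r, bins)
  expect_equal(sum(tr$values), sum(r$mapq >= 1), tolerance = 1e-9)
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  bins <- toy_bins(2)
  r <- data.frame(chrom = c("chr1", "chrUn"), start = c(0, 0),
                  end = c(100, 100), mapq = 30)
  expect_warning(tr <- count_reads(r, bins), "skipped")
  expect_equal(sum(tr$values), 1)
})

test_that("blacklist exclusion flags any 1-bp overlap and is idempotent", {
  bins <- toy_bins(2)
  expect_identical(
    as.data.frame(apply_blacklist(bins, GenomicRanges::GRanges())),
    as.data.frame(bins))

  bl <- granges0("chr1", 4999, 5001)
  b2 <- apply_blacklist(bins, bl)
  expect_equal(S4Vectors::mcols(b2)$excluded, c(TRUE, TRUE))
  expect_equal(S4Vectors::mcols(b2)$reason, c("blacklist", "blacklist"))

  # idempotent and order-independent
  b3 <- apply_blacklist(b2, bl)
  expect_identical(as.data.frame(b2), as.data.frame(b3))

  bins10 <- toy_bins(10)
  b4 <- apply_blacklist(bins10, granges0("chr1", 12000, 18000))
  # brute-force interval oracle per bin
  expect_flag <- vapply(seq_len(10), function(i)
    brute_overlap_bp((i - 1) * 5000, i * 5000, 12000, 18000) >= 1, logical(1))
  expect_equal(S4Vectors::mcols(b4)$excluded, expect_flag)
  expect_equal(sum(usable_bins(b4)), 8L)
})

test_that("bin tracks validate ranges by kind", {
  expect_error(bin_track(c(0.5, 1.2), "pbs"), "\\[0, 1\\]")
  expect_error(bin_track(c(-0.5), "raw_counts"), "non-negative")
  expect_error(bin_track(c(-1.5), "diff_pbs"), "\\[-1, 1\\]")
  t <- bin_track(c(0.2, NA, 1), "pbs")
  expect_s3_class(t, "BinTrack")
  expect_length(t, 3L)
})

test_that("bedGraph write/read round-trips bin values", {
  bins <- toy_bins(5)
  tr <- bin_track(c(1.25, 0, 3.5, NA, 2.125), "raw_counts")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bin_track(tr, bins, f)
  back <- read_bin_values(f, bins)
  expect_equal(back$values[-4], tr$values[-4], tolerance = 1e-6)
  expect_true(is.na(back$values[4]))
})

test_that("coverage-style bedGraph import averages within bins", {
  bins <- toy_bins(1)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t2500\t2", "chr1\t2500\t5000\t4"), f)
  v <- read_bin_values(f, bins)
  expect_equal(v$values, 3)
  # with a read_length the mean coverage becomes a read-count equivalent
  v2 <- read_bin_values(f, bins, read_length = 100)
  expect_equal(v2$values, 3 * 5000 / 100)
})

test_that("thresholded BED export matches a counting oracle", {
  set.seed(7)
  n <- 200
  bins <- toy_bins(n)
  vals <- runif(n)
  tr <- bin_track(vals, "pbs")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bin_track(tr, bins, f, format = "bed_threshold", threshold = 0.9)
  expect_equal(length(readLines(f)), sum(vals > 0.9))

  # simple case: {1.0, 0.95, 0.2} at 0.9 -> 2 intervals
  b3 <- toy_bins(3)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bin_track(bin_track(c(1, 0.95, 0.2), "pbs"), b3, f2,
                  format = "bed_threshold", threshold = 0.9)
  expect_equal(length(readLines(f2)), 2L)

  # all-missing track -> empty body
  f3 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bin_track(bin_track(rep(NA_real_, 3), "pbs"), b3, f3,
                  track_line = "track type=bedGraph")
  expect_equal(readLines(f3), "track type=bedGraph")
})

test_that("SAM alignments are counted through the standard reader", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  bins <- toy_bins(2)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 30, "100M", "*", 0, 0,
          strrep("A", 100), "*", sep = "\t"),
    paste("r2", 0, "chr1", 4951, 30, "100M", "*", 0, 0,
          strrep("A", 100), "*", sep = "\t"),
    paste("r3", 0, "chr1", 201, 0, "100M", "*", 0, 0,
          strrep("A", 100), "*", sep = "\t")), sam)
  tr <- count_reads(sam, bins)
  expect_equal(tr$values, c(1.5, 0.5))  # r3 dropped (MAPQ 0), r2 split
})
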
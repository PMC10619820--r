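# a hand-built empirical distribution / fit pair where the density ratio is
# controlled exactly, for formula arithmetic checks
.toy_emp_fit <- function(ratios) {
  # cells centred on 1..k with unit width; choose f = ratio * lam * f*
  k <- length(ratios)
  breaks <- seq(0.5, k + 0.5, by = 1)
  fit <- structure(list(alpha = 2, beta = 0.5, lam = 0.9, theta = 2,
                        omega2 = 0, q = 0, converged = TRUE,
                        theta_quantile = 0.5),
                   class = "GammaBackgroundFit")
  fstar <- binpbs:::.gamma_cell_mass(breaks, 2, 0.5)
  dens <- ratios * fit$lam * fstar
  emp <- structure(list(grid = 1:k, density = dens,
                        cdf = cumsum(dens), breaks = breaks,
                        widths = rep(1, k), n = 1000L, bin_width = 1),
                   class = "EmpiricalDistribution")
  list(emp = emp, fit = fit)
}

test_that("PBS follows the density-excess formula with clamping", {
  tf <- .toy_emp_fit(c(1, 10, 0.5, 100))
  counts <- bin_track(c(1, 2, 3, 4), "rescaled_counts")
  p <- compute_pbs(counts, tf$emp, tf$fit)
  # f = lam f* -> 0; f = 10 lam f* -> 0.9; f < lam f* -> clamped to 0
  expect_equal(p$values, c(0, 0.9, 0, 0.99), tolerance = 1e-12)
  expect_equal(p$kind, "pbs")
})

test_that("identical counts always receive identical PBS", {
  set.seed(23)
  sim <- simulate_counts(simulation_spec(5e4, seed = 23))
  emp <- empirical_distribution(sim$track)
  fit <- fit_background(sim$track, emp = emp)
  p <- compute_pbs(sim$track, emp, fit)
  v <- round(sim$track$values, 6)
  dup <- duplicated(v) | duplicated(v, fromLast = TRUE)
  if (any(dup)) {
    agg <- tapply(p$values[dup], v[dup], function(x) diff(range(x)))
    expect_true(all(agg == 0))
  }
  expect_true(all(p$values >= 0 & p$values <= 1, na.rm = TRUE))
})

test_that("computed PBS matches the generating posterior on separated mixtures", {
  sim <- simulate_counts(simulation_spec(1e5, lam = 0.8, signal_fold = 8,
                                         signal_shape = 6, seed = 24))
  emp <- empirical_distribution(sim$track)
  fit <- fit_background(sim$track, emp = emp)
  p <- compute_pbs(sim$track, emp, fit, bins = sim$bins)
  x <- sim$track$values
  err <- abs(p$values - sim$posterior(x))
  dec <- cut(x, quantile(x, 0:10 / 10), include.lowest = TRUE, labels = FALSE)
  expect_lt(max(tapply(err, dec, mean, na.rm = TRUE)), 0.05)
})

test_that("differential PBS is exact bin-wise subtraction", {
  a <- bin_track(c(1, 0.5, NA, 0.2), "pbs")
  b <- bin_track(c(0, 0.5, 0.1, NA), "pbs")
  d <- differential_pbs(a, b)
  expect_equal(d$values, c(1, 0, NA, NA))
  expect_equal(d$kind, "diff_pbs")
  # exact antisymmetry
  expect_identical(d$values, -differential_pbs(b, a)$values)
  expect_error(differential_pbs(a, bin_track(0.1, "pbs")), "scaffold")
  expect_error(differential_pbs(a, bin_track(c(1, 1, 1, 1), "raw_counts")),
               "PBS")
})

test_that("thresholding uses strict inequality, optionally on |value|", {
  p <- bin_track(c(0.95, 0.9, 0.1), "pbs")
  expect_equal(threshold_pbs(p, 0.9), c(TRUE, FALSE, FALSE))
  d <- bin_track(c(0.95, -0.95, 0.5), "diff_pbs")
  expect_equal(threshold_pbs(d, 0.9, absolute = TRUE), c(TRUE, TRUE, FALSE))
  set.seed(25)
  v <- runif(1000)
  expect_equal(sum(threshold_pbs(bin_track(v, "pbs"), 0.73)), sum(v > 0.73))
})

test_that("category summaries partition usable bins", {
  set.seed(26)
  v <- runif(2e4)
  s <- summarize_categories(bin_track(v, "pbs"),
                            edges = seq(0.2, 0.8, by = 0.2))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-9)
  expect_equal(s$fractions, rep(0.2, 5), tolerance = 0.02)
  s2 <- summarize_categories(bin_track(rep(1, 10), "pbs"))
  expect_equal(s2$fractions, c(0, 0, 1))
  expect_error(summarize_categories(bin_track(v, "pbs"),
                                    edges = c(0.9, 0.1)), "increasing")
})

test_that("near-bimodal tracks leave the moderate category almost empty", {
  sim <- simulate_counts(simulation_spec(1e5, lam = 0.9, signal_fold = 8,
                                         signal_shape = 8, seed = 27))
  emp <- empirical_distribution(sim$track)
  fit <- fit_background(sim$track, emp = emp)
  p <- compute_pbs(sim$track, emp, fit, bins = sim$bins)
  s <- summarize_categories(p, edges = c(0.1, 0.9))
  expect_lt(s$fractions[2], 0.05)
})

test_that("the PBS matrix selects bins overlapping the region", {
  bins <- toy_bins(10)
  tr <- bin_track(seq(0, 0.9, by = 0.1), "pbs", sample = "s1")
  m <- pbs_matrix(tr, bins, "chr1:0-5000")
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m[1, 1], 0)
  # mid-bin boundaries include any overlapping bin
  m2 <- pbs_matrix(list(tr, tr), bins, "chr1:2500-12500")
  expect_equal(ncol(m2), 3L)
  expect_equal(nrow(m2), 2L)
  # column count equals a brute-force interval count
  n_over <- sum(vapply(seq_len(10), function(i)
    brute_overlap_bp((i - 1) * 5000, i * 5000, 2500, 12500) > 0, logical(1)))
  expect_equal(ncol(m2), n_over)
  expect_error(pbs_matrix(tr, bins, "chrX:0-5000"), "scaffold")
  f <- withr::local_tempfile(fileext = ".tsv")
  pbs_matrix(tr, bins, "chr1:0-20000", path = f)
  expect_equal(ncol(read.delim(f, row.names = 1)), 4L)
})
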
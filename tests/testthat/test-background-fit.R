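test_that("empirical distribution normalises and matches the ECDF", {
  set.seed(12)
  v <- rgamma(1e5, 3, rate = 0.1)
  emp <- empirical_distribution(v)
  expect_equal(sum(emp$density * emp$widths), 1, tolerance = 1e-9)
  expect_false(is.unsorted(emp$cdf))
  expect_equal(emp$cdf[length(emp$cdf)], 1)
  # F(theta) ~ 0.5 at the sample median
  med <- median(v)
  i <- findInterval(med, emp$breaks)
  expect_equal(emp$cdf[i], 0.5, tolerance = 0.01)
  # grid refinement barely moves F at the median (ECDF oracle)
  emp2 <- empirical_distribution(v, n_grid = 2000)
  i2 <- findInterval(med, emp2$breaks)
  expect_lt(abs(emp2$cdf[i2] - mean(v <= med)), 0.01)
  expect_lt(abs(emp$cdf[i] - mean(v <= med)), 0.01)

  expect_error(empirical_distribution(rep(NA_real_, 10)), "missing")
  expect_error(empirical_distribution(rep(2, 2000)), "identical")
  expect_warning(empirical_distribution(rgamma(500, 3, 1)), "1000")
})

test_that("the CvM criterion vanishes in the self-consistency limit", {
  set.seed(13)
  v <- rgamma(1e6, 2.5, rate = 0.2)
  emp <- empirical_distribution(v)
  th <- median(v)
  w_true <- cvm_objective(2.5, 0.2, 1, emp, th)
  expect_lt(w_true, 1e-4)
  # lambda ~ 0 leaves the full empirical CDF unexplained
  expect_gt(cvm_objective(2.5, 0.2, 1e-9, emp, th), w_true)
  expect_error(cvm_objective(-1, 0.2, 1, emp, th), "range")
  expect_error(cvm_objective(2.5, 0.2, 1.2, emp, th), "range")
})

test_that("the generating parameters sit at a local minimum of the criterion", {
  set.seed(14)
  v <- rgamma(2e5, 3, rate = 0.1)
  emp <- empirical_distribution(v)
  th <- median(v)
  w0 <- cvm_objective(3, 0.1, 1, emp, th)
  # brute-force grid scan around the truth
  for (mult in c(0.8, 1.2)) {
    expect_gt(cvm_objective(3 * mult, 0.1, 1, emp, th), w0)
    expect_gt(cvm_objective(3, 0.1 * mult, 1, emp, th), w0)
  }
})

test_that("background fit recovers pure-gamma parameters", {
  set.seed(15)
  v <- rgamma(1e5, 3, rate = 0.1)
  fit <- fit_background(v)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 3) / 3, 0.1)
  expect_gte(fit$lam, 0.97)
  expect_equal(fit$theta, unname(quantile(v, 0.5)))
  expect_error(fit_background(rep(0, 5000)), "zero")
})

test_that("mixture background fit recovers the background fraction", {
  sim <- simulate_counts(simulation_spec(2e5, lam = 0.8, signal_fold = 5,
                                         seed = 42))
  fit <- fit_background(sim$track)
  expect_equal(fit$lam, 0.8, tolerance = 0.03)
  expect_lt(abs(fit$alpha - 3) / 3, 0.1)
})

test_that("the fit is scale equivariant", {
  set.seed(16)
  v <- rgamma(1e5, 3, rate = 0.1)
  f1 <- fit_background(v)
  f2 <- fit_background(v * 4)
  expect_equal(f2$alpha, f1$alpha, tolerance = 0.05)
  expect_equal(f2$lam, f1$lam, tolerance = 0.02)
  expect_equal(f2$beta, f1$beta / 4, tolerance = 0.05)
})

test_that("fit quality is zero for an exact match and grows with misfit", {
  # construct an empirical distribution whose density above theta equals
  # lambda * f* exactly: q must be 0 by construction
  set.seed(17)
  v <- rgamma(2e5, 3, rate = 0.1)
  emp <- empirical_distribution(v)
  fit <- structure(list(alpha = 3, beta = 0.1, lam = 1,
                        theta = median(v), omega2 = 0, q = NA,
                        converged = TRUE, theta_quantile = 0.5),
                   class = "GammaBackgroundFit")
  emp_exact <- emp
  keep <- emp$grid > fit$theta
  emp_exact$density[keep] <-
    binpbs:::.gamma_cell_mass(emp$breaks, 3, 0.1)[keep] / emp$widths[keep]
  # with the density matched exactly on the grid, q reduces to the analytic
  # background mass beyond the last histogram break
  expect_equal(fit_quality(emp_exact, fit),
               pgamma(emp$breaks[length(emp$breaks)], 3, rate = 0.1,
                      lower.tail = FALSE),
               tolerance = 1e-12)

  # q flags background overshoot, so the constructed misfit must be
  # LIGHTER-tailed than the fitted gamma: truncating the counts leaves the
  # fitted background mass beyond the cutoff as pure excess, close to the
  # analytic tail mass 1 - F*(cutoff)
  q_good <- fit_quality(emp, fit)
  expect_lt(q_good, 0.05)
  set.seed(18)
  vt <- pmin(rgamma(2e5, 3, rate = 0.1), 60)
  fitt <- fit_background(vt)
  expect_gt(fitt$q, 0.05)              # classified as a poor fit
  expect_gt(fitt$q, q_good)
  expect_equal(fitt$q, 1 - pgamma(60, 3, rate = 0.1), tolerance = 0.3)
})

test_that("q is stable under grid refinement when dominated by real misfit", {
  set.seed(19)
  vu <- runif(2e5, 10, 50)    # light-tailed: q is systematic, not noise
  qs <- vapply(c(500, 1000, 2000, 4000), function(g) {
    emp <- empirical_distribution(vu, n_grid = g)
    fit_background(vu, n_grid = g, emp = emp)$q
  }, numeric(1))
  expect_lt(max(qs) / min(qs), 1.2 / 0.8)  # within 20% of each other
  # for a well-specified background q is noise-dominated but stays well
  # below the good-fit bound at every grid resolution
  v <- rgamma(2e5, 3, rate = 0.1)
  qg <- vapply(c(500, 1000, 2000, 4000), function(g)
    fit_background(v, n_grid = g)$q, numeric(1))
  expect_true(all(qg < 0.05))
})

test_that("fit parameters export as a readable TSV", {
  set.seed(20)
  fit <- fit_background(rgamma(2e4, 3, rate = 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fit(fit, f)
  tab <- read.delim(f)
  expect_equal(tab$alpha, fit$alpha)
  expect_equal(tab$q, fit$q)
})
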
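#' Empirical distribution of rescaled counts
#'
#' Fixed-width histogram density f(x) and empirical CDF F(x) on
#' \code{n_grid} equal cells spanning [0, 99.9th percentile], plus one
#' overflow cell up to the sample maximum. The density integrates to 1; the
#' CDF is stored at cell right edges and reaches exactly 1.
#'
#' @param counts BinTrack of rescaled counts, or a numeric vector
#' @param n_grid number of regular histogram cells (default 1000)
#' @return an \code{EmpiricalDistribution}: \code{grid} (cell midpoints),
#'   \code{density}, \code{cdf}, \code{breaks}, \code{widths}, \code{n},
#'   \code{bin_width}
#' @export
empirical_distribution <- function(counts, n_grid = 1000L) {
  v <- if (inherits(counts, "BinTrack")) counts$values else as.numeric(counts)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("all values are missing")
  if (length(unique(v)) == 1L) stop("all values are identical")
  if (length(v) < 1000L)
    warning("fewer than 1000 bins contribute to the empirical distribution")

  hi <- unname(stats::quantile(v, 0.999, names = FALSE))
  if (hi <= 0) hi <- max(v) * 0.999
  breaks <- seq(0, hi, length.out = n_grid + 1L)
  w <- breaks[2] - breaks[1]
  top <- max(max(v), hi + w)          # overflow cell [hi, top]
  breaks <- c(breaks, top)
  cell <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(cell, nbins = length(breaks) - 1L)
  widths <- diff(breaks)
  dens <- cnt / (length(v) * widths)
  cdf <- cumsum(cnt) / length(v)
  structure(list(grid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                 density = dens, cdf = cdf, breaks = breaks,
                 widths = widths, n = length(v), bin_width = w),
            class = "EmpiricalDistribution")
}

#' @export
print.EmpiricalDistribution <- function(x, ...) {
  cat(sprintf("EmpiricalDistribution: %d cells (+overflow), n=%d, width=%.4g\n",
              length(x$grid) - 1L, x$n, x$bin_width))
  invisible(x)
}

#' Modified Cramer-von-Mises criterion
#'
#' The fitting objective for the gamma background:
#' \deqn{\omega^2 = \int_{-\infty}^{\theta} [F(x) - \lambda F^*(x;\alpha,\beta)]^2 \, dF^*(x;\alpha,\beta)}
#' where F is the empirical CDF, F* the gamma CDF with shape \eqn{\alpha}
#' and rate \eqn{\beta}, and \eqn{\lambda} the background fraction.
#' Evaluated by midpoint quadrature on the histogram grid, restricted to
#' cells at or below \eqn{\theta}.
#'
#' @param alpha gamma shape (> 0)
#' @param beta gamma rate (> 0)
#' @param lam background fraction in (0, 1]
#' @param emp EmpiricalDistribution of the full data
#' @param theta fitting threshold (the data median by default upstream)
#' @return the scalar objective value
#' @export
cvm_objective <- function(alpha, beta, lam, emp, theta) {
  stopifnot(inherits(emp, "EmpiricalDistribution"))
  if (alpha <= 0 || beta <= 0 || lam <= 0 || lam > 1)
    stop("parameters out of range: need alpha, beta > 0 and lam in (0, 1]")
  keep <- emp$grid <= theta
  x <- emp$grid[keep]
  # empirical CDF evaluated at cell midpoints; dF* as the exact gamma mass
  # of each cell (midpoint quadrature of the squared deviation only)
  Fm <- (emp$cdf - emp$density * emp$widths / 2)[keep]
  dFs <- .gamma_cell_mass(emp$breaks, alpha, beta)[keep]
  sum((Fm - lam * stats::pgamma(x, shape = alpha, rate = beta))^2 * dFs)
}

# exact gamma probability mass of each histogram cell
.gamma_cell_mass <- function(breaks, alpha, beta) {
  p <- stats::pgamma(breaks, shape = alpha, rate = beta)
  diff(p)
}

#' Fit the gamma background to the low-count half of the data
#'
#' Estimates the background parameters (shape \eqn{\alpha}, rate
#' \eqn{\beta}) and background fraction \eqn{\lambda} by minimising the
#' modified Cramer-von-Mises criterion over counts at or below the
#' threshold \eqn{\theta} (the \code{theta_quantile} sample quantile;
#' median by default). Low counts are assumed background-dominated, which
#' holds for any reasonable ChIP. Optimisation is derivative-free
#' (Nelder-Mead) on transformed parameters (log \eqn{\alpha}, log
#' \eqn{\beta}, logit \eqn{\lambda}) from a method-of-moments start on the
#' sub-threshold data, with multistart; the best objective is kept.
#'
#' @param counts BinTrack of rescaled counts, or numeric vector
#' @param theta_quantile quantile defining \eqn{\theta} (default 0.5; can
#'   be lowered when more than half the genome is enriched)
#' @param n_grid histogram cells for the empirical distribution
#' @param emp optional precomputed EmpiricalDistribution of the same data
#' @return a \code{GammaBackgroundFit}: \code{alpha}, \code{beta},
#'   \code{lam}, \code{theta}, \code{omega2}, \code{q} (residual fit
#'   quality, filled by \code{\link{fit_quality}}), \code{converged},
#'   \code{theta_quantile}
#' @export
fit_background <- function(counts, theta_quantile = 0.5, n_grid = 1000L,
                           emp = NULL) {
  v <- if (inherits(counts, "BinTrack")) counts$values else as.numeric(counts)
  v <- v[!is.na(v)]
  if (length(v) < 100L) stop("too few values to fit a background")
  if (all(v == 0)) stop("all counts are zero; degenerate input")
  if (theta_quantile <= 0 || theta_quantile >= 1)
    stop("theta_quantile must lie in (0, 1)")
  if (is.null(emp)) emp <- empirical_distribution(v, n_grid = n_grid)
  theta <- unname(stats::quantile(v, theta_quantile, names = FALSE))

  sub <- v[v <= theta & v > 0]
  m <- mean(sub); s2 <- stats::var(sub)
  a0 <- max(m^2 / s2, 1e-2); b0 <- max(m / s2, 1e-8)
  l0 <- min(0.995, max(0.05,
        theta_quantile / stats::pgamma(theta, shape = a0, rate = b0)))

  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2]); l <- stats::plogis(p[3])
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e10)
    cvm_objective(a, b, min(l, 1 - 1e-9), emp, theta)
  }
  starts <- list(
    c(log(a0), log(b0), stats::qlogis(l0)),
    c(log(a0 * 2), log(b0 * 2), stats::qlogis(min(0.99, l0))),
    c(log(a0 * 0.5), log(b0 * 0.5), stats::qlogis(0.7)),
    c(log(a0), log(b0 / 1.5), stats::qlogis(0.9)))
  # The criterion is weighted by the *fitted* CDF, so a degenerate optimum
  # exists where lambda -> 0 and the gamma collapses to a spike at zero
  # (omega2 -> 0 with no data explained). A candidate is only admissible
  # if its background accounts for at least half of the observed sub-theta
  # mass: lambda * F*(theta) >= 0.5 * F(theta).
  femp_theta <- mean(v <= theta)
  best <- NULL; best_any <- NULL
  for (p0 in starts) {
    o <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    mass <- stats::plogis(o$par[3]) *
      stats::pgamma(theta, shape = exp(o$par[1]), rate = exp(o$par[2]))
    if (is.null(best_any) || o$value < best_any$value) best_any <- o
    if (mass >= 0.5 * femp_theta &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) && is.null(best_any))
    stop("background optimisation failed for every start")
  degenerate <- is.null(best)
  if (degenerate) {
    warning("all optimisation starts ended in a degenerate background ",
            "(lambda * F*(theta) < F(theta)/2); fit flagged not converged")
    best <- best_any
  }

  fit <- structure(list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                        lam = min(stats::plogis(best$par[3]), 1),
                        theta = theta, omega2 = best$value, q = NA_real_,
                        converged = best$convergence == 0 && !degenerate,
                        theta_quantile = theta_quantile),
                   class = "GammaBackgroundFit")
  fit$q <- fit_quality(emp, fit)
  fit
}

#' @export
print.GammaBackgroundFit <- function(x, ...) {
  cat(sprintf(paste0("GammaBackgroundFit: alpha=%.4g beta=%.4g lambda=%.4g ",
                     "theta=%.4g omega2=%.3g q=%.4g (%s fit)%s\n"),
              x$alpha, x$beta, x$lam, x$theta, x$omega2, x$q,
              if (!is.na(x$q) && x$q < 0.05) "good" else "poor",
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Residual-area fit quality
#'
#' Integrates, over count values above \eqn{\theta} where the scaled
#' fitted density exceeds the empirical density, the excess
#' \eqn{\lambda f^*(x;\alpha,\beta) - f(x)}. The background is fitted on
#' the bottom half of the data, so this measures how badly it overshoots
#' the top half; a good fit has \code{q < 0.05}.
#'
#' @param emp EmpiricalDistribution of the data the fit was made on
#' @param fit GammaBackgroundFit
#' @return the scalar residual area q
#' @export
fit_quality <- function(emp, fit) {
  stopifnot(inherits(emp, "EmpiricalDistribution"),
            inherits(fit, "GammaBackgroundFit"))
  keep <- emp$grid > fit$theta
  # cell-averaged fitted density (exact gamma mass / cell width)
  fstar <- .gamma_cell_mass(emp$breaks, fit$alpha, fit$beta)[keep] /
    emp$widths[keep]
  excess <- pmax(0, fit$lam * fstar - emp$density[keep])
  # beyond the last break the empirical density is identically zero, so any
  # remaining fitted mass is pure excess (exact closed form)
  tail_mass <- fit$lam *
    stats::pgamma(emp$breaks[length(emp$breaks)], shape = fit$alpha,
                  rate = fit$beta, lower.tail = FALSE)
  sum(excess * emp$widths[keep]) + tail_mass
}

#' Write fit parameters as a TSV
#' @param fit GammaBackgroundFit
#' @param path output path
#' @return the path, invisibly
#' @export
write_fit <- function(fit, path) {
  df <- data.frame(alpha = fit$alpha, beta = fit$beta, lambda = fit$lam,
                   theta = fit$theta, omega2 = fit$omega2, q = fit$q,
                   converged = fit$converged)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
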
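# Bayesian inference for a Pearson correlation from (r_obs, n).
#
# Likelihood: the exact sampling density of the sample correlation r of n
# bivariate-normal observations with population correlation rho
# (Fisher/Hotelling reduced likelihood),
#   f(r | rho, n) = (n-2) Gamma(n-1) (1-rho^2)^((n-1)/2) (1-r^2)^((n-4)/2)
#                   / (sqrt(2 pi) Gamma(n-1/2) (1-rho r)^(n-3/2))
#                   * 2F1(1/2, 1/2; (2n-1)/2; (rho r + 1)/2).
# Prior: "stretched beta" on (-1, 1) with width kappa, i.e. a symmetric
# Beta(1/kappa, 1/kappa) rescaled to (-1, 1); kappa = 1 is uniform.

# Gauss hypergeometric 2F1(a, b; c; z) for 0 <= z < 1 with all-positive
# series terms (a, b, c > 0); plain series, relative tolerance 1e-15.
hyp2f1_pos <- function(a, b, cc, z) {
  vapply(z, function(zz) {
    if (zz < 0 || zz >= 1) stop("hyp2f1_pos needs z in [0, 1)")
    term <- 1; s <- 1
    for (k in 0:5000) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * zz
      s <- s + term
      if (term < s * 1e-15) return(s)
    }
    s
  }, numeric(1))
}

#' Exact sampling density of a sample correlation
#'
#' Density of the Pearson sample correlation coefficient of `n`
#' bivariate-normal observations with population correlation `rho`,
#' evaluated via its hypergeometric closed form with log-space guards.
#' Vectorized over `rho` (the use case: likelihood scans over a parameter
#' grid at fixed observed `r`).
#'
#' @param r observed sample correlation, in (-1, 1).
#' @param n sample size, >= 3.
#' @param rho population correlation(s), in (-1, 1).
#' @param log return the log-density?
#' @return numeric vector, one density per `rho`.
#' @export
dcorr_sample <- function(r, n, rho, log = FALSE) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop_invalid("'r' must be a single value in (-1, 1)")
  if (n < 3) stop_invalid("'n' must be >= 3")
  if (any(abs(rho) >= 1)) stop_invalid("'rho' must lie in (-1, 1)")
  z <- (rho * r + 1) / 2
  lf <- log(n - 2) + lgamma(n - 1) - lgamma(n - 0.5) - 0.5 * log(2 * pi) +
    ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r) + log(hyp2f1_pos(0.5, 0.5, n - 0.5, z))
  if (log) lf else exp(lf)
}

#' Stretched-beta prior density on a correlation
#'
#' Symmetric Beta(1/kappa, 1/kappa) distribution rescaled from (0, 1) to
#' (-1, 1). `kappa = 1` gives the uniform prior; smaller `kappa`
#' concentrates mass near 0 (in the limit the alternative collapses onto
#' the null), larger `kappa` pushes mass to the endpoints.
#'
#' @param rho value(s) in (-1, 1).
#' @param kappa positive prior width.
#' @param log return the log-density?
#' @export
dstretched_beta <- function(rho, kappa = 1, log = FALSE) {
  if (kappa <= 0) stop_invalid("'kappa' must be positive")
  a <- 1 / kappa
  lf <- (a - 1) * log1p(-rho^2) - (2 * a - 1) * base::log(2) - lbeta(a, a)
  lf[abs(rho) >= 1] <- -Inf
  if (log) lf else exp(lf)
}

#' Posterior distribution of a Pearson correlation
#'
#' Grid-quadrature posterior of rho given an observed sample correlation,
#' combining the exact reduced likelihood with a stretched-beta prior of
#' width `kappa`. Summaries are the posterior median and the central
#' (equal-tail) credible interval.
#'
#' @param r_obs observed correlation, in (-1, 1).
#' @param n sample size, >= 3.
#' @param kappa stretched-beta prior width (default 1 = uniform).
#' @param side `"both"` (default), `"positive"` or `"negative"` for a
#'   sign-truncated posterior.
#' @param level credible level.
#' @param n_grid grid resolution on (-1, 1).
#' @return a `posterior_summary` for rho.
#' @examples
#' rho_posterior(0.3, 50)
#' @export
rho_posterior <- function(r_obs, n, kappa = 1, side = "both", level = 0.95,
                          n_grid = 4001L) {
  side <- match.arg(side, c("both", "positive", "negative"))
  eps <- 1e-6
  lo <- if (side == "positive") 0 else -1 + eps
  hi <- if (side == "negative") 0 else 1 - eps
  grid <- seq(lo, hi, length.out = n_grid)
  lp <- dcorr_sample(r_obs, n, grid, log = TRUE) +
    dstretched_beta(grid, kappa, log = TRUE)
  dens <- exp(lp - max(lp))
  z <- cumtrapz1(grid, dens)
  dens <- dens / z[length(z)]
  qs <- grid_quantile(grid, dens, c((1 - level) / 2, 0.5, (1 + level) / 2))
  new_posterior_summary(qs[2], qs[c(1, 3)], level, grid, dens, "rho")
}

#' Default Bayes factor for a Pearson correlation
#'
#' BF10 compares H1 (stretched-beta prior of width `kappa` on rho) against
#' H0: rho = 0, as the ratio of the marginal likelihood of the observed
#' correlation under H1 to its likelihood at rho = 0. Directional variants
#' use the mass-ratio identity with prior sign probability 1/2. At
#' `kappa -> 0` the alternative collapses onto the null and the Bayes
#' factor tends to 1.
#'
#' @inheritParams rho_posterior
#' @return a `bf_result`.
#' @examples
#' bf_correlation(0.4, 40)
#' @export
bf_correlation <- function(r_obs, n, kappa = 1, side = "both") {
  side <- match.arg(side, c("both", "positive", "negative"))
  prior <- structure(list(width = kappa, side = side), class = "jzs_prior")
  f <- function(rho) dcorr_sample(r_obs, n, rho) * dstretched_beta(rho, kappa)
  ip <- stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 0)$value
  im <- stats::integrate(f, -1, 0, rel.tol = 1e-9, abs.tol = 0)$value
  bf10 <- (ip + im) / dcorr_sample(r_obs, n, 0)
  if (side == "both") return(new_bf_result(bf10, "10", prior))
  p_side <- if (side == "positive") ip / (ip + im) else im / (ip + im)
  new_bf_result(bf10 * p_side / 0.5,
                if (side == "positive") "+0" else "-0", prior)
}

#' Posterior for Cramer's phi-squared from a contingency table
#'
#' Places a symmetric Dirichlet(alpha) prior on the joint cell
#' probabilities of an R x C table under multinomial sampling, draws from
#' the conjugate Dirichlet posterior, and transforms each draw into
#' Cramer's phi-squared,
#' `phi2 = sum_ij (p_ij - p_i. p_.j)^2 / (p_i. p_.j) / (min(R, C) - 1)`,
#' a normalized association measure in `[0, 1]` that for a 2 x 2 table
#' equals the squared Pearson phi correlation. Summaries are Monte Carlo.
#'
#' @param counts matrix of nonnegative integer counts, at least 2 x 2.
#' @param alpha Dirichlet concentration per cell (default 1).
#' @param n_draws number of posterior draws (default 50000).
#' @param seed optional integer seed for reproducible draws.
#' @param level credible level.
#' @return a `posterior_summary` for phi-squared; `values` are the draws.
#' @examples
#' phi2_posterior(matrix(c(30, 10, 8, 32), 2, 2), seed = 1)
#' @export
phi2_posterior <- function(counts, alpha = 1, n_draws = 50000L, seed = NULL,
                           level = 0.95) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop_invalid("'counts' must be at least a 2 x 2 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("'counts' must hold nonnegative integers")
  if (sum(counts) < 1) stop_invalid("all-zero table: association undefined")
  if (alpha <= 0) stop_invalid("'alpha' must be positive")
  R <- nrow(counts); C <- ncol(counts); K <- R * C
  a_post <- as.numeric(counts) + alpha
  draws <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_draws * K, shape = rep(a_post, each = n_draws)),
                nrow = n_draws)
    g / rowSums(g)
  })
  # row/column marginals per draw (cells stored column-major: cell (i,j) at
  # column (j-1)*R + i of `draws`)
  pr <- sapply(1:R, function(i) rowSums(draws[, (0:(C - 1)) * R + i, drop = FALSE]))
  pc <- sapply(1:C, function(j) rowSums(draws[, (j - 1) * R + (1:R), drop = FALSE]))
  chi2 <- 0
  for (i in 1:R) for (j in 1:C) {
    e <- pr[, i] * pc[, j]
    chi2 <- chi2 + (draws[, (j - 1) * R + i] - e)^2 / e
  }
  phi2 <- chi2 / (min(R, C) - 1)
  qs <- stats::quantile(phi2, c((1 - level) / 2, 0.5, (1 + level) / 2),
                        names = FALSE)
  new_posterior_summary(qs[2], qs[c(1, 3)], level, phi2,
                        rep(1, length(phi2)), "phi2")
}
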
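# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoid-rule cumulative integral of y over ordered grid x, starting at 0.
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Quantiles of a continuous density tabulated on a grid, by linear
# interpolation of the trapezoid CDF. Returns values on the grid scale.
grid_quantile <- function(x, dens, probs) {
  cdf <- cumtrapz1(x, dens)
  tot <- cdf[length(cdf)]
  if (!is.finite(tot) || tot <= 0) stop("degenerate density: total mass is not positive")
  cdf <- cdf / tot
  # guard against flat stretches (ties) in the CDF
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], x[keep], xout = probs, rule = 2, ties = "ordered")$y
}

# Quantiles of a weighted sample (weights need not be normalized).
weighted_quantile <- function(x, w, probs) {
  if (length(x) == 1L) return(rep(x, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  sw <- sum(w)
  # midpoint convention so a point mass sits at its own quantile
  cm <- cumsum(w) / sw - w / (2 * sw)
  keep <- c(TRUE, diff(cm) > 0)
  stats::approx(cm[keep], x[keep], xout = probs, rule = 2, ties = "ordered")$y
}

stop_invalid <- function(...) stop(..., call. = FALSE)
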
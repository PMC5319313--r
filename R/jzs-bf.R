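# Default (JZS) Bayes factors for t-tests from summary statistics.
#
# Under H1 the standardized effect delta carries a Cauchy(0, r) prior,
# equivalently a scale mixture delta | g ~ N(0, g) with
# g ~ inverse-gamma(1/2, r^2/2). Marginalizing delta first, the t-statistic
# given g follows a scaled central t:
#   p(t | g) = f_t(t / sqrt(1 + Neff g); nu) / sqrt(1 + Neff g),
# so the marginal likelihood under H1 is a one-dimensional integral over g
# of analytic terms, and BF10 = p(t | H1) / f_t(t; nu). Directional Bayes
# factors use the mass-ratio identity
#   BF(+)0 = BF10 * P(delta > 0 | data, H1) / P(delta > 0 | H1),
# with prior sign probability 1/2 for the zero-centred prior; the posterior
# sign mass comes from integrating the noncentral-t likelihood against the
# Cauchy prior over each half-line.

# Marginal likelihood of t under H1 (Cauchy(0, r) on delta), integrating
# over the mixing scale. With g = r^2 / x^2 and x half-normal (so that
# 1/g ~ Gamma(1/2, r^2/2), i.e. g inverse-gamma), the integrand
#   2 phi(x) f_t(t / s; nu) / s,   s = sqrt(1 + Neff r^2 / x^2),
# is smooth and well-scaled for every r > 0, including widths near 0.
jzs_marginal <- function(t, nu, neff, r, rel_tol = 1e-10) {
  integrand <- function(x) {
    s <- sqrt(1 + neff * r^2 / x^2)
    2 * stats::dnorm(x) * stats::dt(t / s, nu) / s
  }
  # split at the transition scale x ~ r sqrt(Neff) so narrow priors keep
  # their small-x structure visible to the adaptive rule
  brk <- min(max(r * sqrt(neff), 1e-300), 1)
  res <- tryCatch({
    lo <- stats::integrate(integrand, 0, brk, rel.tol = rel_tol, abs.tol = 0)
    hi <- stats::integrate(integrand, brk, Inf, rel.tol = rel_tol, abs.tol = 0)
    if (lo$message != "OK" || hi$message != "OK") NULL
    else list(value = lo$value + hi$value, message = "OK")
  }, error = function(e) NULL)
  if (is.null(res) || res$message != "OK") {
    # fallback: doubled-resolution fixed grid on the same transform
    x <- seq(1e-8, 12, length.out = 40001)
    s <- sqrt(1 + neff * r^2 / x^2)
    val <- sum(2 * stats::dnorm(x) * stats::dt(t / s, nu) / s) * (x[2] - x[1])
    return(val)
  }
  res$value
}

# posterior mass on delta > 0 under H1, and the H1 marginal via the
# delta-space route (noncentral-t likelihood against the Cauchy prior)
jzs_sign_mass <- function(t, nu, neff, r, rel_tol = 1e-9) {
  f <- function(d) dnct(t, nu, d * sqrt(neff), log = FALSE) * stats::dcauchy(d, 0, r)
  ip <- stats::integrate(f, 0, Inf, rel.tol = rel_tol, abs.tol = 0)
  im <- stats::integrate(f, -Inf, 0, rel.tol = rel_tol, abs.tol = 0)
  if (ip$message != "OK" || im$message != "OK")
    stop("sign-mass quadrature did not converge: ", ip$message, " / ", im$message)
  list(pos = ip$value, neg = im$value)
}

new_bf_result <- function(value, pair, prior) {
  structure(list(value = value, pair = pair, prior = prior), class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  lab <- c("10" = "BF10", "+0" = "BF+0", "-0" = "BF-0")[x$pair]
  val <- if (x$value >= 100) signif(x$value, 3) else round(x$value, 3)
  cat(sprintf("%s = %s  (Cauchy width r = %.4g, side = %s)\n",
              lab, format(val), x$prior$width, x$prior$side))
  invisible(x)
}

#' Two-sided default Bayes factor for a t-test
#'
#' Computes the JZS Bayes factor BF10 comparing H1 (Cauchy(0, r) prior on
#' the standardized effect size delta) against the point null H0: delta = 0,
#' from the summary statistics alone. The marginal likelihood under H1 is
#' obtained by adaptive quadrature over the inverse-gamma mixing scale of
#' the Cauchy prior (relative tolerance 1e-10); at prior width 0 the
#' hypotheses coincide and the Bayes factor is exactly 1.
#'
#' @param summary a [ttest_summary()].
#' @param prior a two-sided [jzs_prior()].
#' @return a `bf_result` with fields `value`, `pair = "10"`, `prior`.
#' @examples
#' bf10_ttest(ttest_summary(4.178, 18, 69))  # about 288
#' @export
bf10_ttest <- function(summary, prior = jzs_prior()) {
  summary <- as_ttest_summary(summary)
  if (!inherits(prior, "jzs_prior")) stop_invalid("'prior' must be a jzs_prior")
  if (prior$side != "both")
    stop_invalid("bf10_ttest needs a two-sided prior; use bf_onesided_ttest for folded priors")
  if (prior$width == 0) return(new_bf_result(1, "10", prior))
  m1 <- jzs_marginal(summary$t, summary$nu, summary$neff, prior$width)
  m0 <- stats::dt(summary$t, summary$nu)
  new_bf_result(m1 / m0, "10", prior)
}

#' One-sided (directional) default Bayes factor for a t-test
#'
#' Folds the Cauchy prior onto one sign of the effect and compares the
#' resulting directional hypothesis against the point null. Computed via
#' the mass-ratio identity
#' `BF(side)0 = BF10 * P(sign | data, H1) / P(sign | H1)` with prior sign
#' probability 1/2, which is cheaper and numerically stabler than
#' integrating a truncated prior directly. A correct directional prediction
#' is rewarded: when the data lean towards the predicted sign,
#' `BF(side)0 > BF10`, up to the factor 2 bound.
#'
#' @param summary a [ttest_summary()].
#' @param prior a [jzs_prior()]; its `side` is overridden by `side` if given.
#' @param side `"positive"` or `"negative"`; defaults to `prior$side`, or the
#'   summary's predicted direction when the prior is two-sided.
#' @return a `bf_result` with `pair` `"+0"` or `"-0"`.
#' @examples
#' bf_onesided_ttest(ttest_summary(4.178, 18, 69), side = "positive")  # about 576
#' @export
bf_onesided_ttest <- function(summary, prior = jzs_prior(), side = NULL) {
  summary <- as_ttest_summary(summary)
  if (!inherits(prior, "jzs_prior")) stop_invalid("'prior' must be a jzs_prior")
  if (is.null(side)) {
    side <- if (prior$side != "both") prior$side
            else if (summary$direction > 0) "positive" else "negative"
  }
  side <- match.arg(side, c("positive", "negative"))
  prior <- jzs_prior(prior$width, side)
  pair <- if (side == "positive") "+0" else "-0"
  if (prior$width == 0) return(new_bf_result(1, pair, prior))
  bf10 <- jzs_marginal(summary$t, summary$nu, summary$neff, prior$width) /
    stats::dt(summary$t, summary$nu)
  sm <- jzs_sign_mass(summary$t, summary$nu, summary$neff, prior$width)
  p_side <- if (side == "positive") sm$pos / (sm$pos + sm$neg)
            else sm$neg / (sm$pos + sm$neg)
  new_bf_result(bf10 * p_side / 0.5, pair, prior)
}

#' Bayes-factor robustness curve over the prior width
#'
#' Evaluates the (directional or two-sided) Bayes factor on a grid of
#' Cauchy prior widths, the standard sensitivity analysis for default
#' Bayes factors. At width 0 the alternative collapses onto the null and
#' the curve equals 1 exactly; the curve's maximum and its location
#' (`argmax_r`) summarize how strongly the conclusion depends on the
#' prior scale.
#'
#' @param summary a [ttest_summary()].
#' @param side `"both"`, `"positive"` or `"negative"`.
#' @param r_grid ordered vector of nonnegative prior widths.
#' @return an object of class `robustness_curve`: a data frame with columns
#'   `r` and `bf`, plus attributes `argmax_r` and `max_bf`.
#' @examples
#' rc <- robustness_curve(ttest_summary(4.178, 18, 69), "positive",
#'                        seq(0, 1.5, by = 0.05))
#' attr(rc, "max_bf"); attr(rc, "argmax_r")
#' @export
robustness_curve <- function(summary, side = "positive", r_grid) {
  summary <- as_ttest_summary(summary)
  side <- match.arg(side, c("both", "positive", "negative"))
  if (length(r_grid) < 1L || any(!is.finite(r_grid)) || any(r_grid < 0) ||
      is.unsorted(r_grid))
    stop_invalid("'r_grid' must be a nonempty sorted vector of nonnegative widths")
  bf <- vapply(r_grid, function(r) {
    if (side == "both") bf10_ttest(summary, jzs_prior(r))$value
    else bf_onesided_ttest(summary, jzs_prior(r), side)$value
  }, numeric(1))
  out <- data.frame(r = r_grid, bf = bf)
  class(out) <- c("robustness_curve", "data.frame")
  attr(out, "argmax_r") <- r_grid[which.max(bf)]
  attr(out, "max_bf") <- max(bf)
  attr(out, "side") <- side
  out
}
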
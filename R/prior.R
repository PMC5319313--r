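# Zero-centred Cauchy (JZS) prior on the standardized effect size.

#' JZS Cauchy prior on a standardized effect size
#'
#' The default (Jeffreys-Zellner-Siow) prior places a Cauchy distribution
#' with location 0 and scale `width` on the standardized effect size delta.
#' `width = 1/sqrt(2)` is the modern default; `width = 1` is Jeffreys's
#' classic "wide" prior; `width = 0` is the degenerate point-null limit
#' under which the alternative collapses onto the null and every Bayes
#' factor equals 1. Directional hypotheses are expressed by *folding* the
#' prior onto one sign (`side = "positive"` or `"negative"`), which halves
#' and renormalizes the prior mass.
#'
#' @param width Cauchy scale on delta, >= 0. Default `2^-0.5`.
#' @param side one of `"both"`, `"positive"`, `"negative"`.
#' @return an object of class `jzs_prior`.
#' @examples
#' jzs_prior()                       # two-sided default, r = 0.707
#' jzs_prior(1, side = "positive")   # folded wide prior
#' @export
jzs_prior <- function(width = 2^-0.5, side = c("both", "positive", "negative")) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width < 0)
    stop_invalid("'width' must be a single nonnegative number")
  side <- match.arg(side)
  structure(list(width = as.numeric(width), side = side), class = "jzs_prior")
}

#' @export
print.jzs_prior <- function(x, ...) {
  cat(sprintf("Cauchy(0, %.4g) prior on delta, side = %s\n", x$width, x$side))
  invisible(x)
}
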
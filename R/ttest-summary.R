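# Sufficient statistics of a one- or two-sample t-test.

#' Summary statistics of a t-test
#'
#' Bundles the sufficient statistics of a one-sample (`n2 = 0`) or
#' independent two-sample t-test: the observed t-statistic, the group
#' sizes, and the predicted direction of the effect. Degrees of freedom
#' and the effective sample size that scales the noncentrality of the
#' sampling distribution are derived:
#' \itemize{
#'   \item one-sample: `nu = n1 - 1`, `Neff = n1`;
#'   \item two-sample: `nu = n1 + n2 - 2`, `Neff = n1 * n2 / (n1 + n2)`.
#' }
#'
#' @param t observed t-statistic.
#' @param n1 first (or only) group size, integer >= 2.
#' @param n2 second group size; 0 (default) denotes a one-sample design.
#' @param direction predicted sign of the effect, +1 or -1.
#' @param id optional study label.
#' @return an object of class `ttest_summary` with fields `t`, `n1`, `n2`,
#'   `nu`, `neff`, `direction`, `id`.
#' @examples
#' ttest_summary(t = 4.178, n1 = 18, n2 = 69)
#' @export
ttest_summary <- function(t, n1, n2 = 0, direction = 1, id = NULL) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop_invalid("'t' must be a single finite number")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || n1 < 2L) stop_invalid("'n1' must be an integer >= 2")
  if (is.na(n2) || n2 < 0L || n2 == 1L)
    stop_invalid("'n2' must be 0 (one-sample) or an integer >= 2")
  nu <- if (n2 == 0L) n1 - 1L else n1 + n2 - 2L
  if (nu < 1L) stop_invalid("degrees of freedom must be >= 1")
  neff <- if (n2 == 0L) as.numeric(n1) else n1 * n2 / (n1 + n2)
  if (!(direction %in% c(-1, 1))) stop_invalid("'direction' must be +1 or -1")
  structure(
    list(t = as.numeric(t), n1 = n1, n2 = n2, nu = as.numeric(nu),
         neff = neff, direction = as.numeric(direction), id = id),
    class = "ttest_summary")
}

#' @export
print.ttest_summary <- function(x, ...) {
  design <- if (x$n2 == 0L) sprintf("one-sample (n = %d)", x$n1)
            else sprintf("two-sample (n1 = %d, n2 = %d)", x$n1, x$n2)
  cat(sprintf("t-test summary%s: t = %.4g, %s, nu = %g, Neff = %.4g\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$t, design, x$nu, x$neff))
  invisible(x)
}

as_ttest_summary <- function(x) {
  if (inherits(x, "ttest_summary")) return(x)
  stop_invalid("expected a 'ttest_summary' object; see ttest_summary()")
}
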
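# Independent oracles used to cross-check the package's quadrature code.
# They deliberately take different computational routes: stats::dt(ncp = )
# (the AS 243-based noncentral-t in base R) with adaptive integration over
# the effect size, and a random-walk Metropolis sampler for posteriors.

# BF10 by brute-force quadrature over delta using base R's noncentral t
oracle_bf10 <- function(t, n1, n2, r) {
  nu <- if (n2 == 0) n1 - 1 else n1 + n2 - 2
  neff <- if (n2 == 0) n1 else n1 * n2 / (n1 + n2)
  f <- function(d) suppressWarnings(stats::dt(t, nu, ncp = d * sqrt(neff))) *
    stats::dcauchy(d, 0, r)
  m1 <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  m1 / stats::dt(t, nu)
}

# posterior draws of delta by random-walk Metropolis on the same model
oracle_delta_mcmc <- function(t, n1, n2, r, n_draws = 50000, seed = 1) {
  nu <- if (n2 == 0) n1 - 1 else n1 + n2 - 2
  neff <- if (n2 == 0) n1 else n1 * n2 / (n1 + n2)
  logpost <- function(d) suppressWarnings(
    stats::dt(t, nu, ncp = d * sqrt(neff), log = TRUE)) +
    stats::dcauchy(d, 0, r, log = TRUE)
  set.seed(seed)
  cur <- t / sqrt(neff)
  lp_cur <- logpost(cur)
  step <- 2.5 * sqrt(1 / neff + cur^2 / (2 * nu))
  draws <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    prop <- cur + stats::rnorm(1, 0, step)
    lp_prop <- logpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) { cur <- prop; lp_cur <- lp_prop }
    draws[i] <- cur
  }
  draws[-(1:2000)]
}

# noncentral-t density by adaptive quadrature of the defining normal/chi
# scale mixture (different integration scheme from the package's fixed
# Gauss-Legendre rule)
oracle_dnct <- function(t, nu, ncp) {
  f <- function(w) w * stats::dnorm(t * w - ncp) *
    stats::dchisq(nu * w^2, nu) * 2 * nu * w
  stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# random but reproducible t-test summaries for property tests
random_summaries <- function(n, seed, t_max = 6, n_max = 200) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    two <- stats::runif(1) < 0.7
    n1 <- sample(5:n_max, 1)
    n2 <- if (two) sample(5:n_max, 1) else 0
    ttest_summary(stats::runif(1, -t_max, t_max), n1, n2)
  })
}
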
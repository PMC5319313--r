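# Bayesian random-effects meta-analysis of standardized effect sizes from
# t-test summary statistics.
#
# Model (per study s, working directly on the sufficient statistics):
#   t_s | delta_s ~ noncentral-t(nu_s, delta_s * sqrt(Neff_s))
#   delta_s = theta + tau * z_s,   z_s ~ N(0, 1)    (non-centred)
#   theta ~ Cauchy(0, theta_prior_scale)
#   tau   ~ half-Cauchy(0, tau_scale)  truncated below at tau_lower_bound
#        or p(tau) proportional to tau^-2 on [tau_lower_bound, tau_upper_bound]
# The noncentral-t likelihood is represented exactly in the sampler through
# the chi-square augmentation u_s ~ chisq(nu_s),
#   t_s | u_s, delta_s ~ Normal(delta_s sqrt(Neff_s) / sqrt(u_s/nu_s),
#                               sd = sqrt(nu_s/u_s)),
# whose marginal over u_s is the noncentral t. Sampling is Gibbs (JAGS),
# with per-chain seeded RNG streams for bit-reproducibility.

meta_model_string <- function(tau_prior) {
  tau_block <- switch(tau_prior,
    half_cauchy = "
  tau ~ dt(0, pow(tau_scale, -2), 1) T(tau_lb,)",
    as_printed = "
  # p(tau) ~ tau^-2 on [tau_lb, tau_ub] via inverse-uniform transform
  v ~ dunif(1 / tau_ub, 1 / tau_lb)
  tau <- 1 / v",
    stop_invalid("unknown tau prior: ", tau_prior))
  paste0("
model {
  for (s in 1:S) {
    u[s] ~ dchisqr(nu[s])
    t[s] ~ dnorm(delta[s] * sqrtN[s] / sqrt(u[s] / nu[s]), u[s] / nu[s])
    z[s] ~ dnorm(0, 1)
    delta[s] <- theta + tau * z[s]
  }
  theta ~ dt(0, pow(theta_scale, -2), 1)", tau_block, "
  tau2 <- pow(tau, 2)
}")
}

#' Configuration for the hierarchical meta-analysis
#'
#' @param tau_prior prior on the heterogeneity SD tau: `"half_cauchy"`
#'   (default; half-Cauchy(0, `tau_scale`)) or `"as_printed"` (the literal
#'   improper `p(tau) ~ tau^-2`, made proper by truncation to
#'   `[tau_lower_bound, tau_upper_bound]`; note that this truncated prior
#'   concentrates nearly all its mass at the lower bound and is strongly
#'   informative towards zero heterogeneity).
#' @param theta_prior_scale Cauchy scale of the prior on the group mean
#'   theta (default 1/2, matching the effect-size prior used per study).
#' @param tau_scale half-Cauchy scale for `tau_prior = "half_cauchy"`.
#' @param chains,warmup,draws MCMC layout: number of chains, adaptation/
#'   burn-in iterations per chain, and kept draws per chain.
#' @param seed integer seed; chain c uses stream seed `seed + c`.
#' @param tau_lower_bound,tau_upper_bound truncation bounds on tau.
#' @return a list of class `meta_config`.
#' @export
meta_config <- function(tau_prior = c("half_cauchy", "as_printed"),
                        theta_prior_scale = 0.5, tau_scale = 0.5,
                        chains = 4L, warmup = 1000L, draws = 1000L,
                        seed = 1L, tau_lower_bound = 0.001,
                        tau_upper_bound = 10) {
  tau_prior <- match.arg(tau_prior)
  stopifnot(theta_prior_scale > 0, tau_scale > 0, chains >= 1, warmup >= 0,
            draws >= 1, tau_lower_bound > 0,
            tau_upper_bound > tau_lower_bound)
  structure(list(tau_prior = tau_prior, theta_prior_scale = theta_prior_scale,
                 tau_scale = tau_scale, chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), tau_lower_bound = tau_lower_bound,
                 tau_upper_bound = tau_upper_bound),
            class = "meta_config")
}

coerce_study_frame <- function(studies) {
  if (inherits(studies, "simulated_studies")) studies <- studies$studies
  studies <- as.data.frame(studies)
  need <- c("study_id", "t", "n1", "n2")
  if (!all(need %in% names(studies)))
    stop_invalid("'studies' must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(studies$study_id)) stop_invalid("study ids must be unique")
  studies
}

#' Fit the Bayesian random-effects meta-analysis
#'
#' Samples the joint posterior of the group mean effect `theta`, the
#' between-study heterogeneity `tau^2`, and the per-study standardized
#' effects `delta_s` from t-test summary statistics, using Gibbs sampling
#' with an exact chi-square augmentation of the noncentral-t likelihood
#' and a non-centred parametrization of the hierarchy. Convergence is
#' checked per parameter (potential scale reduction and effective sample
#' size); violations are flagged on the returned object and raised as
#' warnings, never silently ignored.
#'
#' @param studies a data frame with columns `study_id`, `t`, `n1`, `n2`
#'   (`n2 = 0` for one-sample designs), e.g. from [simulate_studies()] or
#'   [read_studies_csv()]; at least 2 studies.
#' @param config a [meta_config()].
#' @return an object of class `hierarchical_posterior` with elements
#'   `theta_draws`, `tau2_draws`, `delta_draws` (matrix, one column per
#'   study), `diagnostics` (per-parameter Rhat and effective sample size),
#'   `converged`, `study_id`, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_studies(n_studies = 10, seed = 7)
#' fit <- fit_meta(sim$studies, meta_config(chains = 2, warmup = 300, draws = 300))
#' summary(fit)
#' }
#' @export
fit_meta <- function(studies, config = meta_config()) {
  studies <- coerce_study_frame(studies)
  if (!inherits(config, "meta_config")) stop_invalid("'config' must be a meta_config")
  S <- nrow(studies)
  if (S < 2L) stop_invalid("need at least 2 studies to identify heterogeneity")
  n1 <- as.integer(studies$n1); n2 <- as.integer(studies$n2)
  if (any(n1 < 2L) || any(n2 < 0L) || any(n2 == 1L))
    stop_invalid("invalid group sizes in 'studies'")
  nu <- ifelse(n2 == 0L, n1 - 1L, n1 + n2 - 2L)
  neff <- ifelse(n2 == 0L, as.numeric(n1), n1 * n2 / (n1 + n2))
  dat <- list(S = S, t = as.numeric(studies$t), nu = as.numeric(nu),
              sqrtN = sqrt(neff), theta_scale = config$theta_prior_scale,
              tau_lb = config$tau_lower_bound)
  if (config$tau_prior == "half_cauchy") dat$tau_scale <- config$tau_scale
  if (config$tau_prior == "as_printed") dat$tau_ub <- config$tau_upper_bound
  inits <- lapply(seq_len(config$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + ch))
  jm <- rjags::jags.model(
    textConnection(meta_model_string(config$tau_prior)), data = dat,
    inits = inits, n.chains = config$chains, quiet = TRUE)
  if (config$warmup > 0) update(jm, config$warmup, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("theta", "tau2", "delta"),
                             n.iter = config$draws, progress.bar = "none")
  m <- as.matrix(sam)
  dn <- paste0("delta[", seq_len(S), "]")
  rhat <- if (config$chains >= 2L)
    coda::gelman.diag(sam, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  else rep(NA_real_, ncol(m))
  neff_mc <- coda::effectiveSize(sam)
  pars <- c("theta", "tau2", dn)
  diagnostics <- data.frame(parameter = pars,
                            rhat = unname(rhat[pars]),
                            n_eff = unname(neff_mc[pars]),
                            stringsAsFactors = FALSE)
  converged <- all(is.na(diagnostics$rhat) | diagnostics$rhat <= 1.01) &&
    all(diagnostics$n_eff >= 400)
  if (!converged)
    warning("meta-analysis sampler flagged: Rhat > 1.01 or n_eff < 400 for ",
            "some parameter(s); inspect $diagnostics", call. = FALSE)
  structure(list(theta_draws = m[, "theta"], tau2_draws = m[, "tau2"],
                 delta_draws = m[, dn, drop = FALSE],
                 diagnostics = diagnostics, converged = converged,
                 study_id = studies$study_id, config = config),
            class = "hierarchical_posterior")
}

#' @export
summary.hierarchical_posterior <- function(object, level = 0.95, ...) {
  p <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qt_ <- function(x) stats::quantile(x, p, names = FALSE)
  g <- rbind(theta = qt_(object$theta_draws), tau2 = qt_(object$tau2_draws))
  colnames(g) <- c("ci_low", "median", "ci_high")
  d <- t(apply(object$delta_draws, 2, qt_))
  colnames(d) <- c("ci_low", "median", "ci_high")
  rownames(d) <- object$study_id
  list(group = g, delta = d, converged = object$converged, level = level)
}

#' @export
print.hierarchical_posterior <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Hierarchical meta-analysis of %d studies (%d draws)\n",
              length(x$study_id), length(x$theta_draws)))
  cat(sprintf("  theta: median %.3f, 95%% CI [%.3f, %.3f]\n",
              s$group["theta", "median"], s$group["theta", "ci_low"],
              s$group["theta", "ci_high"]))
  cat(sprintf("  tau^2: median %.4f, 95%% CI [%.4f, %.4f]\n",
              s$group["tau2", "median"], s$group["tau2", "ci_low"],
              s$group["tau2", "ci_high"]))
  if (!x$converged) cat("  WARNING: convergence diagnostics flagged\n")
  invisible(x)
}

#' Shrinkage comparison of hierarchical and individual estimates
#'
#' Pairs each study's hierarchical posterior summary with its
#' individual-study (no-pooling) posterior summary and quantifies the pull
#' towards the group mean as the shrinkage fraction
#' `1 - |hier_median - theta_hat| / |indiv_median - theta_hat|` (0 when the
#' individual median already sits at the group mean, i.e. the denominator
#' is below 1e-6).
#'
#' @param post a `hierarchical_posterior` from [fit_meta()].
#' @param individual list of `posterior_summary` objects (one per study,
#'   same order as the fit, e.g. from [delta_posterior()]).
#' @param level credible level for the hierarchical intervals.
#' @return data frame with one row per study: individual and hierarchical
#'   medians and intervals plus the shrinkage fraction.
#' @export
shrinkage_table <- function(post, individual, level = 0.95) {
  if (!inherits(post, "hierarchical_posterior"))
    stop_invalid("'post' must come from fit_meta()")
  S <- length(post$study_id)
  if (length(individual) != S)
    stop_invalid("'individual' must have one posterior per study (", S, ")")
  p <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  theta_hat <- stats::median(post$theta_draws)
  hier <- t(apply(post$delta_draws, 2, stats::quantile, probs = p, names = FALSE))
  im <- vapply(individual, function(x) x$median, numeric(1))
  il <- vapply(individual, function(x) x$ci_low, numeric(1))
  ih <- vapply(individual, function(x) x$ci_high, numeric(1))
  denom <- abs(im - theta_hat)
  shrink <- ifelse(denom < 1e-6, 0, 1 - abs(hier[, 2] - theta_hat) / denom)
  out <- data.frame(study_id = post$study_id,
                    indiv_median = im, indiv_lo = il, indiv_hi = ih,
                    hier_median = hier[, 2], hier_lo = hier[, 1],
                    hier_hi = hier[, 3], shrinkage = shrink,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
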
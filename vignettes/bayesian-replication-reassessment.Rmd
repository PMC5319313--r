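---
title: "Methods: default Bayesian reassessment of replication studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: default Bayesian reassessment of replication studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesrep)
```

# The problem

Large collections of preregistered replication studies are usually
summarized with p-values and confidence intervals, which cannot separate
*absence of evidence* from *evidence of absence*. bayesrep implements the
complementary default-Bayesian toolkit for such a corpus, working entirely
from summary statistics: per-study effect-size posteriors, default Bayes
factors against the point null (two-sided and directional), prior-width
sensitivity curves, and a hierarchical random-effects meta-analysis that
pools standardized effects across studies.

# Models

## JZS model for t-tests

A one- or two-sample t-statistic with `nu` degrees of freedom and true
standardized effect size `delta` (population Cohen's d) follows a
noncentral t distribution with noncentrality `delta * sqrt(Neff)`, where
`Neff = n1` (one-sample) or `n1 n2 / (n1 + n2)` (two-sample). Because
`(t, nu, Neff)` are sufficient for `delta` once the study means and
variances carry the standard noninformative nuisance prior
`p(mu, sigma) ~ sigma^-2`, the package never needs raw data: the
noncentral-t density of the observed t *is* the likelihood of `delta`
(`dnct()`, computed by Gauss-Legendre quadrature of the exact normal/chi
scale mixture in log space, so it stays finite and accurate far into the
tails and for noncentralities of at least 50).

Under H1, `delta ~ Cauchy(0, r)` — the Jeffreys-Zellner-Siow default with
modern default width `r = 1/sqrt(2)`. The Bayes factor

\[
\mathrm{BF}_{10} = \frac{\int f_{\mathrm{nct}}(t;\nu,\delta\sqrt{N_{\mathrm{eff}}})\,
  \mathrm{Cauchy}(\delta;0,r)\,d\delta}{f_t(t;\nu)}
\]

is evaluated through the equivalent mixture representation
`delta | g ~ N(0, g)`, `g ~ inverse-gamma(1/2, r^2/2)`, under which the
marginal of `t` given `g` is an analytic scaled central t; the remaining
one-dimensional integral over the mixing scale is done by adaptive
quadrature (relative tolerance 1e-10, split at the transition scale
`x = r * sqrt(Neff)` so that very narrow priors remain accurate). At
`r = 0` the alternative coincides with the null and every Bayes factor is
exactly 1, by construction rather than by quadrature.

Directional ("folded") hypotheses use the mass-ratio identity
`BF(+)0 = BF10 * P(delta > 0 | data, H1) / (1/2)`, with the posterior sign
mass obtained by integrating the noncentral-t likelihood against the prior
over each half-line. This is cheaper and numerically stabler than
integrating a truncated prior directly, and it makes the sign
decomposition `BF+0 + BF-0 = 2 BF10` hold to numerical identity.

The effect-size posterior (`delta_posterior()`) is computed on a grid:
a pilot pass on a wide range centred at `t/sqrt(Neff)` provides posterior
moments, and the final grid of 4001 points spans the median plus/minus six
posterior SDs. Medians and equal-tail intervals interpolate the trapezoid
CDF linearly, which also settles ties at the median. The variance-explained
transform is `rho2 = p1 p2 delta^2 / (1 + p1 p2 delta^2)` with the group
proportions `p1, p2`; for one-sample designs the package uses the analogue
`delta^2 / (1 + delta^2)` and flags it in the result metadata, since no
standard one-sample convention exists.

## Correlations and contingency tables

For a correlation study only `(r_obs, n)` are needed: the exact
Fisher/Hotelling sampling density of the sample correlation given the
population correlation `rho` (a Gauss hypergeometric form with
all-positive series terms, evaluated with log-space guards) is combined
with a *stretched beta* prior — a symmetric Beta(1/kappa, 1/kappa)
rescaled to (-1, 1). `kappa = 1` (uniform) is the default of the default-
Bayes-factor lineage; it is configurable because published analyses do not
always state it.

For an R x C contingency table the package places a symmetric
Dirichlet(alpha, default 1) prior on the joint cell probabilities under
multinomial sampling and transforms conjugate posterior draws into
Cramer's `phi^2 = chi^2(p) / (min(R, C) - 1)`, which lies in [0, 1] and
for 2 x 2 tables equals the squared Pearson phi correlation. Summaries are
Monte Carlo (default 50 000 seeded draws) because `phi^2` of a Dirichlet
vector has no convenient closed form. The joint-multinomial scheme is a
choice: fixed-margin schemes exist, give somewhat different posteriors,
and published figures rarely state which was used — the package therefore
does not claim to reproduce any particular published `phi^2` interval
numerically.

## Hierarchical random-effects meta-analysis

For a set of S t-test studies the effects are tied together:

\[
t_s \mid \delta_s \sim \mathrm{nct}(\nu_s, \delta_s\sqrt{N_{\mathrm{eff},s}}),\qquad
\delta_s \sim \mathrm{Normal}(\theta, \tau^2),\qquad
\theta \sim \mathrm{Cauchy}(0, 1/2).
\]

`theta` is the group-level mean effect and `tau^2` the between-study
heterogeneity. Sampling uses JAGS (Gibbs) with two structural devices:

* an **exact chi-square augmentation** of the noncentral-t likelihood —
  `u_s ~ chisq(nu_s)` and `t_s | u_s ~ Normal(delta_s sqrt(Neff_s) /
  sqrt(u_s/nu_s), sd = sqrt(nu_s/u_s))` — whose marginal over `u_s` is the
  noncentral t, so the summary-statistic likelihood is represented without
  approximation and without needing a noncentral-t sampler;
* the **non-centred parametrization** `delta_s = theta + tau z_s`,
  `z_s ~ N(0,1)`, which avoids the funnel geometry that makes small-`tau`
  hierarchies hard to sample.

Defaults are 4 chains of 1000 warmup + 1000 kept draws, per-chain seeded
RNG streams (bit-reproducible given the seed), and convergence gates of
potential scale reduction <= 1.01 and effective sample size >= 400 per
reported parameter; violations set `converged = FALSE` and raise a
warning, never a silent pass.

**The prior on tau.** Two options are provided. The package default is
half-Cauchy(0, 1/2) on `tau`, truncated below at 0.001. The literal
scale-free form `p(tau) ~ tau^-2` is also offered (`tau_prior =
"as_printed"`), made proper by truncation to [0.001, 10] via an
inverse-uniform transform. It should be used with care: that density
integrates to a point mass at its lower cutoff (the implied prior median
of `tau` is about 0.002), so it overwhelms any realistic data and drives
`tau^2` to the boundary — in our prototyping it also mixes poorly under
Gibbs (split-chain PSRF above 2). We read the scale-free form as most
plausibly a slip for a log-uniform prior on the variance and therefore do
not make it the default; both choices are recorded in the fitted object's
config.

`shrinkage_table()` pairs each study's hierarchical interval with its
individual-study interval and reports the shrinkage fraction
`1 - |hier - theta_hat| / |indiv - theta_hat|` (defined as 0 when the
individual median already sits at the group mean). Dependence between
t-tests that share an experiment is deliberately ignored — with a few
dozen studies there is no information to support topic-level parameters.

# The synthetic study-set generator

`simulate_studies()` draws study sets with exactly the generative
structure the hierarchical model assumes: `delta_s ~ N(theta, tau^2)`,
group sizes uniform on a range, designs two-sample with a fixed
probability, and `t_s` from the noncentral-t sampling distribution. The
defaults *are* the reference conditions of the replication corpus the
package targets: 38 studies, `theta = 0.05`, `tau = 0.14` (so `tau^2`
about 0.02), group sizes 20-120, and 80% two-sample designs (most
replication t-tests compare two groups; the exact fraction is not
critical and is configurable). Predicted directions are fixed to +1,
matching the convention of recoding every effect so its prediction is
positive. `fixture_special_issue_like()` freezes one such set (with the
worked-example anchor `t = 4.178, n1 = 18, n2 = 69` pinned as study 1)
for deterministic tests and examples; it is clearly synthetic and is not
the deposited data of any real collection.

What the generator does *not* emulate: duplicate studies from shared
experiments, non-normal group-level effect distributions, selective
reporting, or correlation/contingency designs under the hierarchy.
Passing recovery and calibration tests therefore demonstrates internal
coherence of the machinery under the model's own assumptions, not
robustness to violations of them.

# Numerical choices

* Noncentral-t log-density: 160-node Gauss-Legendre rule on the interval
  `mode +/- 12` Laplace scales of the strictly concave log-integrand
  (closed-form mode), log-sum-exp accumulation; agrees with adaptive
  quadrature of the defining mixture to ~1e-10 relative.
* Bayes-factor quadrature: adaptive, relative tolerance 1e-10 with a
  doubled-resolution fixed-grid fallback; posterior grids: 4001 points,
  two-pass placement, trapezoid normalization (within 1e-6 of unit mass).
* Monte Carlo: `phi^2` uses 50 000 draws by default; every stochastic
  routine takes an explicit seed and restores the caller's RNG state.
* Degenerate inputs: `r = 0` or `kappa -> 0` return Bayes factor 1;
  all-zero contingency tables, empty draw vectors, nonpositive degrees of
  freedom, and out-of-range correlations raise invalid-input errors.

# Problem sizes used in the shipped checks

The test suite exercises the machinery at deliberately modest sizes that
a laptop reproduces in about a minute: oracle cross-checks on 20
randomized summaries; a parameter-recovery study of 20 replicates of
38-study sets at 4 chains x 500 draws (95% intervals for `theta` and
`tau^2` required to cover truth in at least 18 of 20); and an interval-
calibration study of 760 null studies (one-sided 95%-interval
false-exclusion rate required to match the nominal 2.5% within three
binomial standard errors). Larger runs only sharpen the same comparisons.

# Known limitations

* Welch/unequal-variance and paired designs beyond the one-sample
  reduction are out of scope, as are informed (non-zero-centred) priors
  and replication-specific Bayes factors.
* Contingency-table *Bayes factors* (as opposed to `phi^2` estimation)
  are not implemented.
* The hierarchical model pools t-test studies only.
* Published interval endpoints produced by other software can differ in
  the third decimal from the grid quadrature used here; the package's
  tolerance conventions (two decimals for medians and intervals, three
  significant digits for large Bayes factors) match common reporting
  practice.
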
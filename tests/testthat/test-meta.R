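# Hierarchical random-effects meta-analysis: reproducibility, limits,
# shrinkage geometry, and diagnostics.

small_cfg <- function(seed = 1, ...) {
  meta_config(chains = 2L, warmup = 500L, draws = 500L, seed = seed, ...)
}

test_that("identical data, config and seed give identical draws", {
  sim <- simulate_studies(n_studies = 12, seed = 9)
  f1 <- suppressWarnings(fit_meta(sim$studies, small_cfg(seed = 4)))
  f2 <- suppressWarnings(fit_meta(sim$studies, small_cfg(seed = 4)))
  expect_identical(f1$theta_draws, f2$theta_draws)
  expect_identical(f1$delta_draws, f2$delta_draws)
  f3 <- suppressWarnings(fit_meta(sim$studies, small_cfg(seed = 5)))
  expect_false(identical(f1$theta_draws, f3$theta_draws))
})

test_that("fewer than two studies is rejected", {
  sim <- simulate_studies(n_studies = 1, seed = 2)
  expect_error(fit_meta(sim$studies, small_cfg()), "at least 2")
})

test_that("identical high-precision studies concentrate theta at the common effect", {
  # three replicates of delta = 0.4 measured with n = 5000 per group
  d <- 0.4; n <- 5000L
  tval <- d * sqrt(n / 2)
  st <- data.frame(study_id = paste0("s", 1:3), t = tval, n1 = n, n2 = n)
  fit <- suppressWarnings(fit_meta(st, small_cfg(seed = 3)))
  expect_equal(median(fit$theta_draws), d, tolerance = 0.05)
  # heterogeneity mass piles near its lower bound
  expect_lt(median(fit$tau2_draws), 0.01)
})

test_that("with enormous fixed heterogeneity the hierarchical fit reduces to no pooling", {
  st <- data.frame(study_id = c("a", "b"), t = c(2.1, -0.4),
                   n1 = c(40L, 55L), n2 = c(45L, 0L))
  cfg <- meta_config(tau_prior = "as_printed", tau_lower_bound = 99,
                     tau_upper_bound = 101, chains = 2L, warmup = 1000L,
                     draws = 2000L, seed = 11)
  fit <- suppressWarnings(fit_meta(st, cfg))
  for (j in 1:2) {
    ind <- delta_posterior(ttest_summary(st$t[j], st$n1[j], st$n2[j]),
                           jzs_prior(100))
    expect_equal(median(fit$delta_draws[, j]), ind$median, tolerance = 0.1)
  }
})

test_that("permuting study order permutes per-study posteriors and leaves the group level unchanged", {
  sim <- simulate_studies(n_studies = 10, seed = 77)
  perm <- c(4, 1, 10, 2, 8, 3, 6, 9, 5, 7)
  f1 <- suppressWarnings(fit_meta(sim$studies, small_cfg(seed = 6)))
  f2 <- suppressWarnings(fit_meta(sim$studies[perm, ], small_cfg(seed = 6)))
  expect_lt(abs(median(f1$theta_draws) - median(f2$theta_draws)), 0.02)
  expect_lt(abs(median(f1$tau2_draws) - median(f2$tau2_draws)), 0.01)
  m1 <- apply(f1$delta_draws, 2, median)
  m2 <- apply(f2$delta_draws, 2, median)
  expect_lt(max(abs(unname(m2) - unname(m1[perm]))), 0.05)
  expect_identical(f2$study_id, f1$study_id[perm])
})

test_that("convergence diagnostics are reported per parameter", {
  sim <- simulate_studies(n_studies = 8, seed = 12)
  fit <- suppressWarnings(fit_meta(sim$studies, small_cfg(seed = 8)))
  expect_true(all(c("theta", "tau2", "delta[1]") %in% fit$diagnostics$parameter))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$n_eff > 0))
  expect_true(is.logical(fit$converged))
})

test_that("shrinkage pulls individual estimates towards the group mean", {
  fx <- fixture_special_issue_like()
  fit <- suppressWarnings(fit_meta(fx, meta_config(chains = 2L, warmup = 500L,
                                                   draws = 1000L, seed = 14)))
  indiv <- lapply(seq_len(nrow(fx)), function(i)
    delta_posterior(ttest_summary(fx$t[i], fx$n1[i], fx$n2[i]), n_grid = 2001L))
  tab <- shrinkage_table(fit, indiv)
  theta_hat <- median(fit$theta_draws)
  between <- (tab$hier_median >= pmin(tab$indiv_median, theta_hat) - 0.01) &
    (tab$hier_median <= pmax(tab$indiv_median, theta_hat) + 0.01)
  expect_gte(mean(between), 0.95)
  # length mismatch is an error
  expect_error(shrinkage_table(fit, indiv[-1]), "one posterior per study")
})
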
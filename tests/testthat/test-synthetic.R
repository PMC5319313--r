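# Synthetic study-set generator: determinism, degenerate limits, and
# distributional fidelity of the generated t-statistics.

test_that("zero heterogeneity makes every hidden effect equal the group mean", {
  sim <- simulate_studies(n_studies = 25, theta = 0.3, tau = 0, seed = 8)
  expect_true(all(sim$truth$delta == 0.3))
})

test_that("the generator is deterministic given a seed", {
  a <- simulate_studies(n_studies = 15, seed = 123)
  b <- simulate_studies(n_studies = 15, seed = 123)
  expect_identical(a$studies, b$studies)
  expect_identical(a$truth, b$truth)
  c <- simulate_studies(n_studies = 15, seed = 124)
  expect_false(identical(a$studies$t, c$studies$t))
})

test_that("standardized t-statistics average to the group mean (law of large numbers)", {
  sim <- simulate_studies(n_studies = 2000, theta = 0.5, tau = 0,
                          design_mix = 1, n_range = c(100L, 100L), seed = 31)
  st <- sim$studies
  neff <- st$n1 * st$n2 / (st$n1 + st$n2)
  d <- st$t / sqrt(neff)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.5), 3 * se)
})

test_that("generated t-statistics follow the analytic noncentral-t law", {
  delta <- 0.35
  sim <- simulate_studies(n_studies = 10000, theta = delta, tau = 0,
                          design_mix = 1, n_range = c(50L, 50L), seed = 202)
  nu <- 98; ncp <- delta * sqrt(25)
  ks <- suppressWarnings(ks.test(sim$studies$t, function(q) pt(q, nu, ncp)))
  expect_gt(ks$p.value, 0.001)
})

test_that("credible intervals from the t-test module are calibrated against the generator", {
  # 200 studies at a known fixed effect; nominal 95% coverage within 4 points
  sim <- simulate_studies(n_studies = 200, theta = 0.3, tau = 0,
                          n_range = c(20L, 120L), seed = 404)
  st <- sim$studies
  covered <- vapply(seq_len(nrow(st)), function(i) {
    dp <- delta_posterior(ttest_summary(st$t[i], st$n1[i], st$n2[i]),
                          n_grid = 2001L)
    dp$ci_low <= 0.3 && 0.3 <= dp$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("the special-issue-like fixture is fixed, valid, and carries the anchor study", {
  fx <- fixture_special_issue_like()
  expect_identical(nrow(fx), 38L)
  expect_identical(fx$t[1], 4.178)
  expect_identical(fx$n1[1], 18L)
  expect_identical(fx$n2[1], 69L)
  expect_identical(fx, fixture_special_issue_like())
  expect_false(anyDuplicated(fx$study_id) > 0)
  ok <- fx$test_type %in% c("one_sample_t", "two_sample_t")
  expect_true(all(ok))
  expect_true(all(fx$n1 >= 2 & (fx$n2 == 0 | fx$n2 >= 2)))
})

test_that("generator rejects invalid configurations", {
  expect_error(simulate_studies(0), "n_studies")
  expect_error(simulate_studies(5, tau = -0.1), "tau")
  expect_error(simulate_studies(5, n_range = c(1L, 50L)), "n_range")
})
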
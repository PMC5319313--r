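# Effect-size posteriors: worked-example anchors, symmetry, truncation,
# and the variance-explained transform.

anchor <- ttest_summary(4.178, 18, 69)

test_that("delta posterior reproduces the worked-example median and interval", {
  dp <- delta_posterior(anchor)
  expect_lt(abs(dp$median - 1.00), 0.02)
  expect_lt(abs(dp$ci_low - 0.47), 0.02)
  expect_lt(abs(dp$ci_high - 1.56), 0.02)
  expect_true(dp$ci_low <= dp$median && dp$median <= dp$ci_high)
})

test_that("delta posterior grid is a normalized density", {
  dp <- delta_posterior(anchor)
  mass <- sum(diff(dp$values) * (dp$weights[-1] + dp$weights[-length(dp$weights)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("at t = 0 the delta posterior is centred and symmetric about zero", {
  dp <- delta_posterior(ttest_summary(0, 40))
  expect_equal(dp$median, 0, tolerance = 1e-3)
  expect_equal(dp$ci_low, -dp$ci_high, tolerance = 1e-3)
})

test_that("folded priors truncate and renormalize the posterior to one sign", {
  dpp <- delta_posterior(ttest_summary(1.2, 25, 25), jzs_prior(side = "positive"))
  expect_true(all(dpp$values >= 0))
  expect_gte(dpp$ci_low, 0)
  dpn <- delta_posterior(ttest_summary(1.2, 25, 25), jzs_prior(side = "negative"))
  expect_true(all(dpn$values <= 0))
  mass <- sum(diff(dpn$values) * (dpn$weights[-1] + dpn$weights[-length(dpn$weights)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("posterior median is nondecreasing in t", {
  meds <- vapply(seq(-3, 3, by = 1), function(tv)
    delta_posterior(ttest_summary(tv, 20, 30))$median, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("grid posterior agrees with an independent Metropolis sampler", {
  for (case in list(c(2.1, 15, 20), c(-1.2, 40, 0), c(0.5, 60, 80))) {
    dp <- delta_posterior(ttest_summary(case[1], case[2], case[3]))
    draws <- oracle_delta_mcmc(case[1], case[2], case[3], 2^-0.5,
                               n_draws = 60000, seed = 42)
    q <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
    expect_lt(abs(dp$median - q[2]), 0.02)
    expect_lt(abs(dp$ci_low - q[1]), 0.05)
    expect_lt(abs(dp$ci_high - q[3]), 0.05)
  }
})

test_that("variance-explained transform reproduces the worked example", {
  r2 <- rho2_from_delta(delta_posterior(anchor), 18, 69)
  expect_lt(abs(r2$median - 0.14), 0.02)
  expect_lt(abs(r2$ci_low - 0.03), 0.02)
  expect_lt(abs(r2$ci_high - 0.29), 0.02)
  expect_true(all(r2$values >= 0 & r2$values < 1))
})

test_that("variance-explained transform has the exact closed-form special cases", {
  # equal groups, single draw delta = 2: rho2 = (1/4 * 4) / (1 + 1/4 * 4) = 1/2
  expect_equal(rho2_from_delta(2, 10, 10)$median, 0.5)
  # all-null draws give exactly zero
  z <- rho2_from_delta(rep(0, 100), 12, 14)
  expect_identical(unname(c(z$median, z$ci_low, z$ci_high)), c(0, 0, 0))
  # one-sample analogue is flagged in the note
  expect_match(rho2_from_delta(c(0.5, 1), 20)$note, "one-sample")
  expect_error(rho2_from_delta(numeric(0), 10, 10), "empty")
})
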
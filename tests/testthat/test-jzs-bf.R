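# JZS Bayes factors for t-tests: worked-example anchors, analytic
# identities, and oracle agreement.

anchor <- ttest_summary(4.178, 18, 69)

test_that("two-sided default Bayes factor reproduces the worked example", {
  bf <- bf10_ttest(anchor)
  expect_equal(bf$value, 288, tolerance = 0.02)
  expect_identical(bf$pair, "10")
})

test_that("directional Bayes factor reproduces the worked example and rewards the prediction", {
  bfp <- bf_onesided_ttest(anchor, side = "positive")
  expect_equal(bfp$value, 576, tolerance = 0.02)
  # correct directional prediction is rewarded relative to the two-sided test
  expect_gt(bfp$value, bf10_ttest(anchor)$value)
})

test_that("a zero prior width collapses the alternative onto the null: BF is exactly 1", {
  for (s in random_summaries(5, seed = 3)) {
    expect_identical(bf10_ttest(s, jzs_prior(0))$value, 1)
    expect_identical(bf_onesided_ttest(s, jzs_prior(0), "positive")$value, 1)
  }
})

test_that("two-sided Bayes factor is invariant under a sign flip of t", {
  for (tval in c(0.3, 1.7, 4.178)) {
    a <- bf10_ttest(ttest_summary(tval, 24, 31))$value
    b <- bf10_ttest(ttest_summary(-tval, 24, 31))$value
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("sign decomposition holds: BF+0 + BF-0 = 2 BF10", {
  for (s in random_summaries(10, seed = 21)) {
    bf10 <- bf10_ttest(s)$value
    bfp <- bf_onesided_ttest(s, side = "positive")$value
    bfm <- bf_onesided_ttest(s, side = "negative")$value
    expect_equal(bfp + bfm, 2 * bf10, tolerance = 1e-8)
  }
})

test_that("at t = 0 the posterior is sign-symmetric so BF+0 equals BF10", {
  s <- ttest_summary(0, 50)
  expect_equal(bf_onesided_ttest(s, side = "positive")$value,
               bf10_ttest(s)$value, tolerance = 1e-8)
  # null-consistent data favour H0
  expect_lt(bf10_ttest(s)$value, 1)
  expect_equal(bf10_ttest(s)$value, oracle_bf10(0, 50, 0, 2^-0.5),
               tolerance = 1e-8)
})

test_that("BF10 is nondecreasing in |t| for fixed design and prior", {
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(tv) bf10_ttest(ttest_summary(tv, 30, 40))$value,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("BF approaches 1 monotonically as the prior width shrinks to 0", {
  rs <- c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2)
  bfs <- vapply(rs, function(r) bf10_ttest(anchor, jzs_prior(r))$value,
                numeric(1))
  expect_true(all(diff(bfs) > 0))     # growing evidence with width near 0
  expect_lt(abs(bfs[1] - 1), 1e-3)    # BF - 1 vanishes linearly in r
})

test_that("robustness curve reproduces the prior-sensitivity figure", {
  rc <- robustness_curve(anchor, "positive", seq(0, 1.5, length.out = 301))
  expect_identical(rc$bf[rc$r == 0], 1)
  expect_equal(attr(rc, "max_bf"), 605, tolerance = 0.02)
  expect_equal(attr(rc, "argmax_r"), 1.0, tolerance = 0.05)
  # the maximum dominates the default-width entry
  expect_gte(attr(rc, "max_bf"),
             bf_onesided_ttest(anchor, side = "positive")$value)
  expect_true(all(is.finite(rc$bf)) && all(rc$bf > 0))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(ttest_summary(2, 1), "n1")
  expect_error(ttest_summary(2, 10, 1), "n2")
  expect_error(jzs_prior(-0.1), "nonnegative")
  expect_error(bf10_ttest(anchor, jzs_prior(0.7, "positive")), "two-sided")
  expect_error(robustness_curve(anchor, "positive", c(0.5, 0.1)), "sorted")
})
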
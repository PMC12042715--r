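test_that("binning counts majors per block and drops the short tail", {
  expect_equal(bin_counts(c(0, 0, 0, 0, 0, 1, 0, 0), 4), c(0L, 1L))
  expect_equal(bin_counts(rep(0L, 20), 4), rep(0L, 5))
  expect_equal(length(bin_counts(make_indicators(10, c(1, 9)), 4)), 2L)
  # the two trailing attempts of a length-10 period are dropped
  expect_equal(sum(bin_counts(make_indicators(10, c(9, 10)), 4)), 0L)
  expect_error(bin_counts(rep(0L, 7), 4), "too short")
})

test_that("the per-attempt rate estimate is the event proportion", {
  ind <- make_indicators(49, c(5, 17, 30, 44))
  expect_equal(estimate_lambda(ind), 4 / 49)
  expect_equal(estimate_lambda(rep(0L, 10)), 0)
  expect_equal(estimate_lambda(rep(1L, 10)), 1)
  # rate times period length recovers the integer event count
  set.seed(81)
  for (rep in 1:20) {
    x <- rbinom(sample(10:100, 1), 1, 0.2)
    expect_equal(estimate_lambda(x) * length(x), sum(x))
  }
})

test_that("chi-squared critical values match the published thresholds and an integration oracle", {
  expect_equal(chi2_critical(1, 0.05), 3.841, tolerance = 1e-3)
  expect_equal(chi2_critical(4, 0.05), 9.487, tolerance = 1e-3)
  expect_equal(chi2_critical(3, 0.05), 7.814, tolerance = 1e-3)
  # independent oracle: numeric integration of the chi-squared density plus
  # root finding on the upper-tail mass
  oracle <- function(df, alpha) {
    dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) /
      (2^(df / 2) * gamma(df / 2))
    uniroot(function(q) stats::integrate(dens, 0, q,
                                         rel.tol = 1e-10)$value - (1 - alpha),
            interval = c(1e-6, 200), tol = 1e-9)$root
  }
  for (df in c(1:10, 15, 20, 30))
    expect_equal(chi2_critical(df, 0.05), oracle(df, 0.05), tolerance = 1e-6)
  expect_error(chi2_critical(0, 0.05), "positive integer")
  expect_error(chi2_critical(3, 1.2), "between 0 and 1")
})

test_that("the index-of-dispersion test matches hand computation and flags clustering", {
  flat <- dispersion_test(c(1, 1, 1, 1))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$verdict, "positive")

  clustered <- dispersion_test(c(0, 0, 0, 0, 5), alpha = 0.05)
  expect_equal(clustered$statistic, 20)  # (n-1) s^2 / xbar = 4 * 5 / 1
  expect_equal(clustered$df, 4L)
  expect_equal(clustered$critical_value, qchisq(0.95, 4))
  expect_equal(clustered$verdict, "negative")

  empty <- dispersion_test(rep(0L, 6))
  expect_true(empty$degenerate)
  expect_equal(empty$verdict, "positive")
  expect_error(dispersion_test(3L), "at least 2")
})

test_that("the verdict agrees with the statistic-threshold invariant on random counts", {
  set.seed(82)
  for (rep in 1:50) {
    counts <- rpois(sample(3:25, 1), runif(1, 0.2, 6))
    res <- dispersion_test(counts, alpha = 0.05)
    if (!res$degenerate) {
      expect_equal(res$verdict == "positive",
                   res$statistic <= res$critical_value)
      expect_equal(res$critical_value, chi2_critical(res$df, res$alpha))
    }
  }
})

test_that("the goodness-of-fit test merges sparse classes as in the worked case", {
  counts <- c(rep(0L, 11), 1L)   # 12 blocks, one event
  res <- gof_test(counts)
  lam <- 1 / 12
  expected <- 12 * c(dpois(0, lam), 1 - dpois(0, lam))
  observed <- c(11, 1)
  expect_equal(res$statistic, sum((observed - expected)^2 / expected))
  expect_equal(res$df, 1L)
  expect_equal(res$critical_value, qchisq(0.95, 1))
  expect_equal(res$verdict, "positive")
})

test_that("the goodness-of-fit test accepts Poisson-proportioned data and rejects clustering", {
  # frequencies close to Poisson(1) proportions over 27 blocks
  balanced <- c(rep(0L, 10), rep(1L, 10), rep(2L, 5), 3L, 3L)
  res <- gof_test(balanced)
  expect_equal(res$verdict, "positive")
  expect_lt(res$statistic, 1)

  clustered <- c(rep(0L, 11), 8L)
  expect_equal(gof_test(clustered)$verdict, "negative")
  expect_true(gof_test(rep(0L, 8))$degenerate)
  expect_error(gof_test(c(0L, 1L)), "at least 5")
})

test_that("plateau detection reports untestable periods and finds the first conforming one", {
  # three periods: short (untestable), clustered (negative), sparse (positive)
  ind <- c(rep(0L, 5),
           c(rep(0L, 12), rep(1L, 4)),
           make_indicators(24, c(3, 20)))
  s <- mma_series(ind)
  per <- segment_periods(s, breakpoints = c(5, 21))
  dec <- detect_plateau(ind, per, gate_config(block_size = 4))
  expect_equal(dec$table$verdict, c("untestable", "negative", "positive"))
  expect_equal(dec$plateau_period, 3L)

  # all positive -> first tested period; all negative -> none
  ind2 <- make_indicators(32, c(5, 13, 21, 29))
  per2 <- segment_periods(mma_series(ind2), breakpoints = 16)
  dec2 <- detect_plateau(ind2, per2, gate_config())
  expect_equal(dec2$plateau_period, 1L)

  ind3 <- c(rep(0L, 12), rep(1L, 4), rep(0L, 12), rep(1L, 4))
  per3 <- segment_periods(mma_series(ind3), breakpoints = 16)
  dec3 <- detect_plateau(ind3, per3, gate_config())
  expect_true(all(dec3$table$verdict == "negative"))
  expect_true(is.na(dec3$plateau_period))

  short <- segment_periods(mma_series(rep(0L, 6)), breakpoints = 3)
  expect_error(detect_plateau(rep(0L, 6), short, gate_config()),
               "no period")
})

test_that("lowering alpha never shrinks the set of Poisson-positive periods", {
  set.seed(83)
  for (rep in 1:15) {
    ind <- rbinom(96, 1, runif(1, 0.05, 0.3))
    per <- segment_periods(mma_series(ind), breakpoints = c(32, 64))
    pos <- function(a) {
      d <- detect_plateau(ind, per, gate_config(alpha = a))
      d$table$period[d$table$verdict == "positive"]
    }
    expect_true(all(pos(0.05) %in% pos(0.01)))
  }
})
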
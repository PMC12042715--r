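test_that("major indicators mark the sample's aborted attempts and need contiguous records", {
  ind <- major_indicators(sample_records())
  expect_equal(which(ind == 1L), c(6L, 13L, 14L, 16L))
  expect_equal(length(ind), 18L)
  expect_equal(major_indicators(make_records(5)), rep(0L, 5))
  expect_equal(major_indicators(make_records(4, majors = 1:4)), rep(1L, 4))
  gap <- make_records(3)
  gap$attempt <- c(1L, 2L, 4L)
  expect_error(major_indicators(gap), "contiguous")
})

test_that("the cumulative MMA reproduces hand-computed proportions", {
  s <- mma_series(make_indicators(19, c(6, 13, 14, 16, 19)))
  expect_equal(s$mma[6], 1 / 6)
  expect_equal(s$mma[19], 5 / 19)
  expect_equal(s$n_major[19], 5L)
  expect_equal(mma_series(rep(0L, 25))$mma, rep(0, 25))
  expect_error(mma_series(integer()), "non-empty")
  expect_error(mma_series(c(0L, 2L)), "binary")
})

test_that("MMA equals a brute-force recount oracle and responds monotonically", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    ind <- rbinom(n, 1, runif(1, 0.05, 0.5))
    got <- mma_series(ind)$mma
    oracle <- vapply(seq_len(n), function(k) sum(ind[seq_len(k)]) / k,
                     numeric(1))
    expect_equal(got, oracle)
    # appending a non-major attempt strictly lowers a positive final MMA
    if (sum(ind) > 0) {
      ext <- mma_series(c(ind, 0L))$mma
      expect_lt(ext[n + 1], got[n])
    }
    # appending a major attempt strictly raises it (when below 1)
    if (got[n] < 1) expect_gt(mma_series(c(ind, 1L))$mma[n + 1], got[n])
  }
})

test_that("period segmentation reproduces the worked drop statistics", {
  ind <- make_indicators(36, c(6, 13, 14, 16, 19, 36))
  per <- segment_periods(mma_series(ind), breakpoints = c(5, 12, 19))
  expect_equal(nrow(per), 4L)
  p4 <- per[per$period == 4, ]
  expect_equal(p4$start, 20L)
  expect_equal(p4$noa, 17L)
  expect_equal(p4$mma_start, 5 / 19)
  expect_equal(p4$mma_end, 6 / 36)
  expect_equal(p4$absolute_drop, 5 / 19 - 1 / 6)
  expect_equal(round_half_up(p4$absolute_drop, 3), 0.096)
  expect_equal(round_half_up(p4$drop_rate, 3), 0.006)
  expect_equal(p4$n_major, 1L)  # only attempt 36 falls inside 20..36
})

test_that("period drops telescope and major counts are conserved over any partition", {
  set.seed(72)
  for (rep in 1:25) {
    n <- sample(20:300, 1)
    ind <- rbinom(n, 1, 0.15)
    s <- mma_series(ind)
    k <- sample(0:5, 1)
    bp <- if (k == 0) NULL else sort(sample(seq_len(n - 1), k))
    per <- segment_periods(s, breakpoints = bp)
    expect_equal(sum(per$n_major), sum(ind))
    expect_equal(sum(per$noa), n)
    expect_equal(sum(per$absolute_drop), s$mma[1] - s$mma[n])
    expect_equal(per$drop_rate * per$noa, per$absolute_drop)
  }
})

test_that("segmentation handles the whole-range and degenerate cases", {
  s <- mma_series(rep(0L, 30))
  whole <- segment_periods(s, breakpoints = NULL)
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$absolute_drop, 0)
  expect_equal(whole$drop_rate, 0)
  expect_error(segment_periods(s, breakpoints = c(10, 35)), "1\\.\\.29")
  expect_error(segment_periods(s, breakpoints = c(10, 10)), "strictly increasing")
})

test_that("the task-time series drops untimed (aborted) attempts", {
  tct <- tct_series(sample_records())
  expect_equal(nrow(tct), 14L)
  expect_equal(max(tct$total_time), 3057L)
  expect_equal(tct$attempt[which.max(tct$total_time)], 4L)
  expect_false(any(tct$attempt %in% c(6, 13, 14, 16)))
  all_major <- make_records(4, majors = 1:4)
  expect_equal(nrow(tct_series(all_major)), 0L)
})

test_that("trend fits recover exact relationships and match a closed-form OLS oracle", {
  x <- 1:10
  lin <- fit_trend(x, 2 * x + 1, model = "linear")
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$slope, 2)
  expect_equal(lin$intercept, 1)

  ex <- fit_trend(x, 3 * exp(-0.05 * x), model = "exponential")
  expect_equal(ex$rate, -0.05, tolerance = 1e-10)
  expect_equal(ex$level, 3, tolerance = 1e-10)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)

  # fixed noise table against hand-computed least squares
  noise <- c(0.3, -0.1, 0.25, -0.4, 0.05, 0.2, -0.3, 0.1, -0.15, 0.05)
  y <- 2 * x + 1 + noise
  fit <- fit_trend(x, y, model = "linear")
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  fitted <- alpha + beta * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, beta, tolerance = 1e-9)
  expect_equal(fit$intercept, alpha, tolerance = 1e-9)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)
})

test_that("linear trend slope and R-squared are invariant to shifting x", {
  set.seed(73)
  x <- 1:40
  y <- 500 - 3 * x + rnorm(40, sd = 20)
  f1 <- fit_trend(x, y, model = "linear")
  f2 <- fit_trend(x + 1000, y, model = "linear")
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("trend fitting rejects bad input and flags constant response", {
  expect_error(fit_trend(1:2, 1:2), "at least 3")
  expect_error(fit_trend(1:5, c(1, 2, -1, 3, 4), model = "exponential"),
               "strictly positive")
  const <- fit_trend(1:5, rep(3, 5), model = "linear")
  expect_true(is.na(const$r_squared))
})
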
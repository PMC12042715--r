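# Per-attempt major-mistake indicators are Bernoulli, hence structurally
# underdispersed relative to Poisson. The dispersion machinery therefore works
# on counts over blocks of consecutive attempts (default 4, roughly one
# training session), which are near-Poisson when the underlying hazard is
# constant and small.

#' Poisson-gate configuration
#'
#' @param block_size Attempts per count block (>= 2; default 4, roughly one
#'   training session).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param test Which conformity test to run: `"dispersion"` (index of
#'   dispersion, default) or `"gof"` (binned chi-squared goodness of fit).
#' @return An object of class `"gate_config"`.
#' @export
gate_config <- function(block_size = 4L, alpha = 0.05,
                        test = c("dispersion", "gof")) {
  test <- match.arg(test)
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 2L)
    stop("'block_size' must be an integer >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  structure(list(block_size = block_size, alpha = alpha, test = test),
            class = "gate_config")
}

#' Bin attempt indicators into block counts
#'
#' Splits a period's 0/1 indicator sequence into consecutive non-overlapping
#' blocks of `block_size` attempts and counts the major mistakes per block. A
#' trailing short block is dropped rather than pooled, so all block counts are
#' identically distributed under a constant hazard.
#'
#' @param indicators Binary 0/1 vector for one period.
#' @param block_size Attempts per block.
#' @return Integer vector of per-block counts.
#' @examples
#' bin_counts(c(0, 0, 0, 0, 0, 1, 0, 0), block_size = 4)
#' @export
bin_counts <- function(indicators, block_size = 4L) {
  indicators <- as.integer(indicators)
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("'block_size' must be >= 2")
  if (length(indicators) < 2L * block_size)
    stop("period too short to bin (need at least 2 blocks); ",
         "use a smaller block size or pool adjacent periods")
  n_blocks <- length(indicators) %/% block_size
  used <- indicators[seq_len(n_blocks * block_size)]
  as.integer(colSums(matrix(used, nrow = block_size)))
}

#' Per-attempt major-mistake rate
#'
#' The maximum-likelihood rate estimate for one period: majors in the period
#' divided by attempts in the period.
#'
#' @param indicators Binary 0/1 vector for one period.
#' @return Rate per attempt.
#' @export
estimate_lambda <- function(indicators) {
  indicators <- as.integer(indicators)
  if (length(indicators) == 0L) stop("'indicators' must be non-empty")
  mean(indicators)
}

#' Upper-tail chi-squared critical value
#'
#' The (1 - alpha) quantile of the chi-squared distribution with `df` degrees
#' of freedom, the rejection threshold for the dispersion and goodness-of-fit
#' statistics.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail significance level in (0, 1).
#' @return The critical value.
#' @examples
#' chi2_critical(1, 0.05)  # 3.841
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || any(df < 1) || any(df %% 1 != 0))
    stop("'df' must be a positive integer")
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1))
    stop("'alpha' must lie strictly between 0 and 1")
  stats::qchisq(1 - alpha, df = df)
}

.dispersion_result <- function(lambda_hat, statistic, df, alpha, method,
                               degenerate = FALSE, n_blocks = NA_integer_,
                               note = NULL) {
  critical <- if (is.na(df)) NA_real_ else chi2_critical(df, alpha)
  verdict <- if (degenerate || is.na(statistic)) "positive" else
    if (statistic <= critical) "positive" else "negative"
  structure(
    list(lambda_hat = lambda_hat, statistic = statistic, df = df,
         critical_value = critical, alpha = alpha, verdict = verdict,
         method = method, degenerate = degenerate, n_blocks = n_blocks,
         note = note),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Poisson %s test: lambda-hat = %.4g per block, statistic = %.4g, df = %s, critical (alpha = %g) = %.4g\n",
              x$method, x$lambda_hat,
              ifelse(is.na(x$statistic), NaN, x$statistic),
              ifelse(is.na(x$df), "NA", x$df), x$alpha,
              ifelse(is.na(x$critical_value), NaN, x$critical_value)))
  cat(sprintf("verdict: %s (%s)%s\n", x$verdict,
              if (x$verdict == "positive")
                "Poisson-conforming; mistakes occur randomly"
              else "overdispersed; mistakes remain systematic",
              if (x$degenerate) " [degenerate: no events observed]" else ""))
  invisible(x)
}

#' Poisson index-of-dispersion test
#'
#' Tests whether block counts are consistent with a Poisson process using the
#' index of dispersion D = (n - 1) s^2 / xbar over n blocks, referred to the
#' upper tail of chi-squared(n - 1). Overdispersion (D above the critical
#' value) signals systematic, non-random mistakes; a "positive" verdict
#' (failure to reject) is read as errors occurring randomly.
#'
#' @param counts Integer vector of per-block counts (>= 2 blocks).
#' @param alpha Upper-tail significance level.
#' @return An object of class `"dispersion_result"` with fields `lambda_hat`
#'   (mean count per block), `statistic`, `df`, `critical_value`, `alpha`,
#'   `verdict` (`"positive"` = Poisson-conforming) and `degenerate` (all-zero
#'   counts, trivially positive).
#' @examples
#' dispersion_test(c(0, 0, 0, 0, 5))  # heavily clustered: negative
#' @export
dispersion_test <- function(counts, alpha = 0.05) {
  counts <- as.integer(counts)
  n <- length(counts)
  if (n < 2L) stop("need at least 2 blocks")
  if (anyNA(counts) || any(counts < 0L)) stop("'counts' must be non-negative")
  xbar <- mean(counts)
  if (xbar == 0)
    return(.dispersion_result(0, NA_real_, n - 1L, alpha, "dispersion",
                              degenerate = TRUE, n_blocks = n,
                              note = "all blocks empty; test vacuous"))
  D <- (n - 1L) * stats::var(counts) / xbar
  .dispersion_result(xbar, D, n - 1L, alpha, "dispersion", n_blocks = n)
}

#' Binned Poisson goodness-of-fit test
#'
#' Chi-squared goodness of fit of the block-count frequencies against
#' Poisson(lambda-hat), using count classes 0, 1 and >= 2. Classes are merged
#' upward (the open top class absorbs its neighbour) until every expected
#' count is at least 1; the degrees of freedom are (classes - 1 - 1) for the
#' estimated rate, floored at 1. If fewer than two usable classes remain the
#' function falls back to [dispersion_test()] with a warning.
#'
#' @param counts Integer vector of per-block counts (>= 5 blocks).
#' @param alpha Upper-tail significance level.
#' @return An object of class `"dispersion_result"` (`method = "gof"`).
#' @export
gof_test <- function(counts, alpha = 0.05) {
  counts <- as.integer(counts)
  n <- length(counts)
  if (n < 5L) stop("need at least 5 blocks for the goodness-of-fit test")
  if (anyNA(counts) || any(counts < 0L)) stop("'counts' must be non-negative")
  lam <- mean(counts)
  if (lam == 0)
    return(.dispersion_result(0, NA_real_, NA_integer_, alpha, "gof",
                              degenerate = TRUE, n_blocks = n,
                              note = "all blocks empty; test vacuous"))
  # classes 0, 1, ..., top class open; start from {0, 1, >=2} and merge the
  # top class downward while any expected count is below 1, never below two
  # classes
  upper <- 2L
  repeat {
    probs <- c(stats::dpois(0:(upper - 1L), lam),
               stats::ppois(upper - 1L, lam, lower.tail = FALSE))
    expected <- n * probs
    if (all(expected >= 1) || upper == 1L) break
    upper <- upper - 1L
  }
  if (length(expected) < 2L) {
    warning("fewer than two usable count classes after merging; ",
            "falling back to the index-of-dispersion test")
    return(dispersion_test(counts, alpha))
  }
  observed <- c(tabulate(counts + 1L, nbins = upper),
                sum(counts >= upper))
  stat <- sum((observed - expected)^2 / expected)
  df <- max(length(expected) - 2L, 1L)
  .dispersion_result(lam, stat, df, alpha, "gof", n_blocks = n)
}

#' Detect the learning-curve plateau (efficient skill threshold)
#'
#' Runs the configured Poisson-conformity test on each learning-curve period
#' in chronological order and returns every period's result together with the
#' first Poisson-positive period: the point at which residual major mistakes
#' are statistically indistinguishable from a random (Poisson) process, read
#' as the operator having reached an efficient skill threshold. Periods too
#' short to bin (or, for the goodness-of-fit test, with fewer than 5 blocks)
#' are reported as `"untestable"`, never silently skipped.
#'
#' @param indicators Binary 0/1 indicator vector for the whole trial.
#' @param periods A `"period_summary"` data frame from [segment_periods()].
#' @param config A [gate_config()].
#' @return An object of class `"plateau_decision"`: a list with `table` (one
#'   row per period: range, per-attempt lambda, statistic, df, critical value,
#'   verdict), `results` (the underlying `"dispersion_result"` objects, `NULL`
#'   where untestable), `plateau_period` (index of the first Poisson-positive
#'   period, or `NA` if none conforms) and `config`.
#' @export
detect_plateau <- function(indicators, periods, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  indicators <- as.integer(indicators)
  periods <- as.data.frame(periods)
  if (nrow(periods) == 0L) stop("'periods' must contain at least one period")
  if (max(periods$end) > length(indicators))
    stop("'periods' extend beyond the indicator sequence")
  min_len <- if (config$test == "gof") 5L * config$block_size else
    2L * config$block_size
  results <- vector("list", nrow(periods))
  rows <- vector("list", nrow(periods))
  for (i in seq_len(nrow(periods))) {
    sub <- indicators[periods$start[i]:periods$end[i]]
    lam_attempt <- estimate_lambda(sub)
    if (length(sub) < min_len) {
      rows[[i]] <- data.frame(
        period = periods$period[i], start = periods$start[i],
        end = periods$end[i], lambda_per_attempt = lam_attempt,
        statistic = NA_real_, df = NA_integer_, critical = NA_real_,
        verdict = "untestable"
      )
      next
    }
    counts <- bin_counts(sub, config$block_size)
    res <- if (config$test == "dispersion")
      dispersion_test(counts, config$alpha) else gof_test(counts, config$alpha)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      period = periods$period[i], start = periods$start[i],
      end = periods$end[i], lambda_per_attempt = lam_attempt,
      statistic = if (is.na(res$statistic)) NA_real_ else res$statistic,
      df = res$df, critical = res$critical_value, verdict = res$verdict
    )
  }
  tab <- do.call(rbind, rows)
  if (all(tab$verdict == "untestable"))
    stop("no period is long enough to test; reduce block_size or pool periods")
  pos <- which(tab$verdict == "positive")
  structure(
    list(table = tab, results = results,
         plateau_period = if (length(pos)) tab$period[pos[1L]] else NA_integer_,
         config = config),
    class = "plateau_decision"
  )
}

#' @export
print.plateau_decision <- function(x, ...) {
  cat(sprintf("Poisson gate (%s test, block size %d, alpha = %g)\n",
              x$config$test, x$config$block_size, x$config$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$plateau_period))
    cat("No period conforms to Poisson randomness: no plateau detected.\n")
  else
    cat(sprintf("Plateau (efficient skill threshold) reached in period %d (attempts %d-%d).\n",
                x$plateau_period,
                x$table$start[x$table$period == x$plateau_period],
                x$table$end[x$table$period == x$plateau_period]))
  invisible(x)
}
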
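#' Binary major-mistake indicators
#'
#' Maps an ordered set of attempt records to a 0/1 sequence whose n-th element
#' is 1 when attempt n contains a major mistake. Requires contiguous attempt
#' numbering from 1, because the sequence position encodes the attempt index.
#'
#' @param records An `"attempt_records"` data frame with contiguous attempt
#'   indices 1..n.
#' @param rubric A [mistake_rubric()].
#' @return An integer vector of 0/1 values, one per attempt.
#' @export
major_indicators <- function(records, rubric = mistake_rubric()) {
  records <- as.data.frame(records)
  idx <- records$attempt
  if (!identical(as.integer(sort(idx)), seq_len(nrow(records))))
    stop("attempt indices must be contiguous from 1; run validate_attempts() ",
         "and repair the data first")
  records <- records[order(idx), , drop = FALSE]
  as.integer(is_major(records, rubric))
}

#' Cumulative major-mistake-average (MMA) series
#'
#' The MMA at attempt n is the proportion of attempts 1..n classified as
#' containing a major mistake: the count of accumulated major-mistake attempts
#' divided by the count of all accumulated attempts. Accumulation always runs
#' from the first attempt of the trial, so the series is a cumulative
#' proportion, not a per-period ratio.
#'
#' @param indicators Binary (0/1) vector of major-mistake indicators, ordered
#'   by attempt.
#' @return An object of class `"mma_series"`: a data frame with columns
#'   `attempt`, `n_major` (cumulative major count) and `mma`.
#' @examples
#' ind <- integer(19); ind[c(6, 13, 14, 16, 19)] <- 1L
#' s <- mma_series(ind)
#' s$mma[c(6, 19)]   # 1/6 and 5/19
#' @export
mma_series <- function(indicators) {
  indicators <- as.integer(indicators)
  if (length(indicators) == 0L) stop("'indicators' must be non-empty")
  if (anyNA(indicators) || !all(indicators %in% c(0L, 1L)))
    stop("'indicators' must be a binary 0/1 sequence")
  n <- seq_along(indicators)
  cum <- cumsum(indicators)
  out <- data.frame(attempt = n, n_major = cum, mma = cum / n)
  class(out) <- c("mma_series", "data.frame")
  out
}

#' @export
print.mma_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("MMA series over %d attempts: %d major-mistake attempt(s), final MMA %.3f\n",
              n, x$n_major[n], x$mma[n]))
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding for reported MMA values and drop rates (base R's
#' `round()` rounds half to even). Internal arithmetic is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Segment the learning curve into periods
#'
#' Partitions attempts 1..n into consecutive learning-curve periods at the
#' supplied breakpoints (the last attempt index of each period except the
#' final one) and computes, for each period, the attempt count (NOA), the
#' cumulative MMA at its endpoints, the absolute MMA drop and the drop rate
#' (absolute drop / NOA).
#'
#' A period's starting MMA is the cumulative MMA at the previous period's last
#' attempt (for the first period, at its own first attempt), and its ending
#' MMA is the cumulative MMA at its own last attempt; drops therefore
#' telescope across any partition.
#'
#' @param series An [mma_series()].
#' @param breakpoints Strictly increasing attempt indices in 1..(n-1), the
#'   last attempt of each period but the final one. Default `c(5, 12, 19, 36,
#'   85)`, the six-period partition of a 132-attempt trial. `NULL` or empty
#'   gives a single whole-range period.
#' @param records Optional `"attempt_records"` data frame from which a mean
#'   task-completion time per period (`tct_average`, untimed attempts
#'   excluded) is added.
#' @return A data frame of class `"period_summary"`, one row per period, with
#'   columns `period`, `start`, `end`, `noa`, `mma_start`, `mma_end`,
#'   `absolute_drop`, `drop_rate`, `n_major` and (optionally) `tct_average`.
#' @examples
#' ind <- integer(36); ind[c(6, 13, 14, 16, 19, 36)] <- 1L
#' segment_periods(mma_series(ind), breakpoints = c(5, 12, 19))
#' @export
segment_periods <- function(series, breakpoints = c(5L, 12L, 19L, 36L, 85L),
                            records = NULL) {
  stopifnot(inherits(series, "mma_series"))
  n <- nrow(series)
  if (is.null(breakpoints) || length(breakpoints) == 0L) {
    breakpoints <- integer()
  } else {
    breakpoints <- as.integer(breakpoints)
    if (anyNA(breakpoints) || any(diff(breakpoints) <= 0))
      stop("'breakpoints' must be strictly increasing attempt indices")
    if (any(breakpoints < 1L) || any(breakpoints >= n))
      stop(sprintf("'breakpoints' must lie in 1..%d (last attempt %d closes the final period implicitly)",
                   n - 1L, n))
  }
  ends <- c(breakpoints, n)
  starts <- c(1L, head(ends, -1L) + 1L)
  k <- length(ends)
  cum <- series$n_major
  v <- series$mma
  mma_start <- v[c(starts[1L], head(ends, -1L))]
  mma_end <- v[ends]
  n_major <- cum[ends] - c(0L, cum[head(ends, -1L)])
  out <- data.frame(
    period = seq_len(k), start = starts, end = ends,
    noa = ends - starts + 1L,
    mma_start = mma_start, mma_end = mma_end,
    absolute_drop = mma_start - mma_end,
    drop_rate = (mma_start - mma_end) / (ends - starts + 1L),
    n_major = n_major
  )
  if (!is.null(records)) {
    tct <- tct_series(records)
    out$tct_average <- vapply(seq_len(k), function(i) {
      tt <- tct$total_time[tct$attempt >= starts[i] & tct$attempt <= ends[i]]
      if (length(tt)) mean(tt) else NA_real_
    }, numeric(1))
  }
  class(out) <- c("period_summary", "data.frame")
  out
}

#' @export
print.period_summary <- function(x, digits = 3L, ...) {
  cat("Learning-curve periods\n")
  disp <- as.data.frame(x)
  for (cl in c("mma_start", "mma_end", "absolute_drop"))
    disp[[cl]] <- round_half_up(disp[[cl]], digits)
  disp$drop_rate <- round_half_up(disp$drop_rate, 4L)
  if ("tct_average" %in% names(disp))
    disp$tct_average <- round_half_up(disp$tct_average, 2L)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Task-completion-time series
#'
#' Extracts the per-attempt total task time, dropping attempts with a total
#' time of zero: in the raw-data convention those are attempts aborted on a
#' major mistake and carry no timing information.
#'
#' @param records An `"attempt_records"` data frame.
#' @return A data frame with columns `attempt` and `total_time` (seconds), in
#'   attempt order.
#' @export
tct_series <- function(records) {
  records <- as.data.frame(records)
  records <- records[order(records$attempt), , drop = FALSE]
  keep <- !is.na(records$total_time) & records$total_time > 0L
  out <- data.frame(attempt = records$attempt[keep],
                    total_time = records$total_time[keep])
  rownames(out) <- NULL
  out
}

#' Fit a linear or exponential trend
#'
#' Ordinary least squares of `y` on `x` (`model = "linear"`), or of `log(y)`
#' on `x` (`model = "exponential"`). For the exponential model the reported
#' coefficients are the level (intercept on the original scale) and the decay
#' rate (slope on the log scale), and R squared is computed on the original
#' `y` scale from the back-transformed fitted values, so the two models'
#' R squared values are directly comparable.
#'
#' @param x Numeric predictor (length >= 3).
#' @param y Numeric response; strictly positive for the exponential model.
#' @param model `"linear"` or `"exponential"`.
#' @return An object of class `"trend_fit"`: a list with `model`,
#'   `intercept`, `slope` (for the exponential model, `level` and `rate` on
#'   the log scale), `r_squared` (`NA` when `y` is constant), and `fitted`.
#' @examples
#' fit_trend(1:10, 3 * exp(-0.05 * (1:10)), model = "exponential")$rate
#' @export
fit_trend <- function(x, y, model = c("linear", "exponential")) {
  model <- match.arg(model)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 points to fit a trend")
  if (anyNA(x) || anyNA(y)) stop("'x' and 'y' must not contain NA")
  if (model == "exponential" && any(y <= 0))
    stop("exponential model requires strictly positive 'y'")
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    fitted <- as.numeric(stats::fitted(fit))
    co <- stats::coef(fit)
    out <- list(model = model, intercept = unname(co[1]),
                slope = unname(co[2]))
  } else {
    fit <- stats::lm(log(y) ~ x)
    co <- stats::coef(fit)
    fitted <- exp(as.numeric(stats::fitted(fit)))
    out <- list(model = model, level = exp(unname(co[1])),
                rate = unname(co[2]))
  }
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  out$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out$fitted <- fitted
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("Linear trend: y = %.4g + %.4g x, R^2 = %s\n",
                x$intercept, x$slope, format(x$r_squared, digits = 3)))
  else
    cat(sprintf("Exponential trend: y = %.4g * exp(%.4g x), R^2 = %s\n",
                x$level, x$rate, format(x$r_squared, digits = 3)))
  invisible(x)
}
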
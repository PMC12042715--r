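.stat_error <- function(msg) {
  stop(errorCondition(msg, class = c("lcgate_stat_error", "error")))
}

#' Full learning-curve analysis
#'
#' Runs the whole pipeline on a set of attempt records: validation, major
#' indicators, the cumulative MMA series, period segmentation with drop
#' statistics, linear TCT and exponential MMA trend fits, and the Poisson
#' gate with plateau detection.
#'
#' @param records An `"attempt_records"` data frame.
#' @param breakpoints Period breakpoints passed to [segment_periods()].
#' @param rubric A [mistake_rubric()].
#' @param gate A [gate_config()].
#' @param validate `"lenient"` (default; warns on issues) or `"strict"`
#'   (errors on issues).
#' @return An object of class `"lc_analysis"`: a list with `validation`,
#'   `indicators`, `mma` (an [mma_series()]), `periods`, `trend_tct`,
#'   `trend_mma`, `gate` (a `"plateau_decision"`), and `provenance`.
#' @examples
#' rec <- read_attempts(system.file("extdata", "anastomosis_sample.csv",
#'                                  package = "lcgate"))
#' an <- analyze_attempts(rec, breakpoints = c(5, 12),
#'                        gate = gate_config(block_size = 3))
#' an$mma$mma[6]
#' @export
analyze_attempts <- function(records,
                             breakpoints = c(5L, 12L, 19L, 36L, 85L),
                             rubric = mistake_rubric(),
                             gate = gate_config(),
                             validate = c("lenient", "strict")) {
  validate <- match.arg(validate)
  report <- validate_attempts(records, mode = validate)
  if (!report$is_clean) {
    if (validate == "strict") {
      msg <- paste0("records failed strict validation (",
                    nrow(report$issues), " issue(s)); first: ",
                    report$issues$message[1])
      stop(msg)
    }
    warning("records carry ", nrow(report$issues),
            " validation issue(s) in lenient mode; proceeding with ",
            "total_score as authoritative")
  }
  ind <- major_indicators(records, rubric)
  series <- mma_series(ind)
  periods <- segment_periods(series, breakpoints = breakpoints,
                             records = records)
  tct <- tct_series(records)
  trend_tct <- if (nrow(tct) >= 3L)
    fit_trend(tct$attempt, tct$total_time, model = "linear") else NULL
  pos <- series$mma > 0
  trend_mma <- if (sum(pos) >= 3L)
    fit_trend(series$attempt[pos], series$mma[pos], model = "exponential")
  else NULL
  gate_res <- tryCatch(
    detect_plateau(ind, periods, gate),
    error = function(e) .stat_error(conditionMessage(e))
  )
  structure(
    list(validation = report, indicators = ind, mma = series,
         periods = periods, tct = tct, trend_tct = trend_tct,
         trend_mma = trend_mma, gate = gate_res,
         provenance = list(
           tool = "lcgate",
           version = as.character(utils::packageVersion("lcgate")),
           n_attempts = length(ind),
           breakpoints = as.integer(breakpoints),
           alpha = gate$alpha, block_size = gate$block_size,
           test = gate$test, validate = validate
         )),
    class = "lc_analysis"
  )
}

#' @export
print.lc_analysis <- function(x, ...) {
  n <- length(x$indicators)
  cat(sprintf("Learning-curve analysis: %d attempts, %d major mistake(s), final MMA %.3f\n\n",
              n, sum(x$indicators), x$mma$mma[n]))
  print(x$periods)
  cat("\n")
  if (!is.null(x$trend_tct)) { cat("TCT "); print(x$trend_tct) }
  if (!is.null(x$trend_mma)) { cat("MMA "); print(x$trend_mma) }
  cat("\n")
  print(x$gate)
  invisible(x)
}

# Machine-readable report: full precision; presentation rounding is applied
# only by the print methods.
.analysis_report_list <- function(x, input_md5 = NULL) {
  gate_rows <- lapply(seq_len(nrow(x$gate$table)), function(i) {
    r <- x$gate$table[i, ]
    list(period = r$period, range = c(r$start, r$end),
         lambda_per_attempt = r$lambda_per_attempt,
         test = x$gate$config$test,
         statistic = r$statistic, df = r$df, critical = r$critical,
         alpha = x$gate$config$alpha, verdict = r$verdict)
  })
  trends <- list()
  if (!is.null(x$trend_tct))
    trends$tct_linear <- list(intercept = x$trend_tct$intercept,
                              slope = x$trend_tct$slope,
                              r_squared = x$trend_tct$r_squared)
  if (!is.null(x$trend_mma))
    trends$mma_exponential <- list(level = x$trend_mma$level,
                                   rate = x$trend_mma$rate,
                                   r_squared = x$trend_mma$r_squared)
  prov <- x$provenance
  if (!is.null(input_md5)) prov$input_md5 <- unname(input_md5)
  list(
    provenance = prov,
    validation = list(n_records = x$validation$n_records,
                      is_clean = x$validation$is_clean,
                      issues = x$validation$issues),
    mma = as.data.frame(x$mma),
    periods = as.data.frame(x$periods),
    trends = trends,
    poisson_gate = list(periods = gate_rows,
                        plateau_period =
                          if (is.na(x$gate$plateau_period)) NULL
                          else x$gate$plateau_period)
  )
}

#' Write analysis outputs to a directory
#'
#' Writes `report.json` (the full analysis, numbers at full precision),
#' `periods.csv` (one row per learning-curve period) and `mma.csv` (the
#' per-attempt MMA table).
#'
#' @param analysis An `"lc_analysis"` object.
#' @param dir Output directory (created if needed).
#' @param input_md5 Optional MD5 of the input file, recorded in provenance.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir, input_md5 = NULL) {
  stopifnot(inherits(analysis, "lc_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.analysis_report_list(analysis, input_md5),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  per <- as.data.frame(analysis$periods)
  cols <- c("period", "start", "end", "noa", "mma_end", "absolute_drop",
            "drop_rate", "n_major",
            if ("tct_average" %in% names(per)) "tct_average")
  utils::write.csv(per[, cols], file.path(dir, "periods.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$mma), file.path(dir, "mma.csv"),
                   row.names = FALSE)
  invisible(dir)
}
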
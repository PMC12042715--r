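# Canonical CSV schema for attempt-level records. One row per attempt; "-" or
# an empty cell means "absent" (never zero: a zero total time is meaningful,
# it marks an attempt that was aborted on a major mistake and not timed).
.attempt_schema <- c(
  "attempt", "date",
  "stage1_mistakes", "stage2_mistakes", "stage3_mistakes", "total_score",
  "stage1_time", "stage2_time", "stage3_time", "total_time"
)

#' Mistake-scoring rubric
#'
#' Encodes the error-scoring system used to classify each simulation attempt:
#' minor technical errors score `minor_points`, critical (non-repairable)
#' errors score `major_points`, and an attempt whose total mistake score
#' reaches `major_threshold` is classified as containing a major mistake.
#'
#' @param minor_points Points per minor mistake (default 1).
#' @param major_points Points per major mistake (default 5).
#' @param major_threshold Total score at or above which an attempt counts as a
#'   major-mistake attempt (default 5).
#' @return An object of class `"mistake_rubric"`.
#' @examples
#' mistake_rubric()
#' @export
mistake_rubric <- function(minor_points = 1L, major_points = 5L,
                           major_threshold = 5L) {
  minor_points <- as.integer(minor_points)
  major_points <- as.integer(major_points)
  major_threshold <- as.integer(major_threshold)
  if (is.na(minor_points) || minor_points < 1L)
    stop("'minor_points' must be an integer >= 1")
  if (is.na(major_points) || major_points < minor_points)
    stop("'major_points' must be >= 'minor_points'")
  if (is.na(major_threshold) || major_threshold < major_points)
    stop("'major_threshold' must be >= 'major_points'")
  structure(
    list(minor_points = minor_points, major_points = major_points,
         major_threshold = major_threshold),
    class = "mistake_rubric"
  )
}

#' @export
print.mistake_rubric <- function(x, ...) {
  cat("Mistake rubric: minor =", x$minor_points, "pt, major =",
      x$major_points, "pt, major-mistake threshold >=", x$major_threshold,
      "pt\n")
  invisible(x)
}

# Parse one character column of integer cells; "-"/"" -> NA; thousands
# separators ("1,159") accepted. Errors name the offending data row.
.parse_int_col <- function(x, col) {
  x <- trimws(x)
  absent <- x == "-" | x == "" | is.na(x)
  cleaned <- gsub(",", "", x, fixed = TRUE)
  suppressWarnings(val <- as.numeric(cleaned))
  bad <- !absent & (is.na(val) | val %% 1 != 0)
  if (any(bad))
    stop(sprintf("column '%s': non-numeric or non-integer value '%s' at data row %d",
                 col, x[which(bad)[1]], which(bad)[1]))
  out <- as.integer(val)
  out[absent] <- NA_integer_
  out
}

.as_attempt_records <- function(df) {
  class(df) <- c("attempt_records", "data.frame")
  df
}

#' Read attempt-level records from CSV
#'
#' Reads a CSV file in the canonical attempt-record schema
#' (`attempt,date,stage1_mistakes,stage2_mistakes,stage3_mistakes,total_score,`
#' `stage1_time,stage2_time,stage3_time,total_time`). Cells rendered `"-"` or
#' left empty are read as absent (`NA`), never as zero, and thousands
#' separators in numeric cells (e.g. `"1,159"`) are accepted. Rows are
#' returned sorted by attempt index.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `"attempt_records"`, one row per attempt.
#' @examples
#' path <- system.file("extdata", "anastomosis_sample.csv", package = "lcgate")
#' rec <- read_attempts(path)
#' head(rec)
#' @export
read_attempts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(.attempt_schema, names(raw))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- data.frame(
      attempt = integer(), date = as.Date(character()),
      stage1_mistakes = integer(), stage2_mistakes = integer(),
      stage3_mistakes = integer(), total_score = integer(),
      stage1_time = integer(), stage2_time = integer(),
      stage3_time = integer(), total_time = integer()
    )
    return(.as_attempt_records(out))
  }
  num_cols <- setdiff(.attempt_schema, c("date"))
  parsed <- lapply(num_cols, function(cl) .parse_int_col(raw[[cl]], cl))
  names(parsed) <- num_cols
  if (anyNA(parsed$attempt))
    stop("column 'attempt': attempt index must be present for every row")
  date_raw <- trimws(raw$date)
  date_raw[date_raw == "-" | date_raw == ""] <- NA
  date <- as.Date(date_raw, format = "%Y-%m-%d")
  if (any(!is.na(date_raw) & is.na(date)))
    warning("some dates could not be parsed as YYYY-MM-DD and were set to NA")
  out <- data.frame(
    attempt = parsed$attempt, date = date,
    stage1_mistakes = parsed$stage1_mistakes,
    stage2_mistakes = parsed$stage2_mistakes,
    stage3_mistakes = parsed$stage3_mistakes,
    total_score = parsed$total_score,
    stage1_time = parsed$stage1_time,
    stage2_time = parsed$stage2_time,
    stage3_time = parsed$stage3_time,
    total_time = parsed$total_time
  )
  out <- out[order(out$attempt), , drop = FALSE]
  rownames(out) <- NULL
  .as_attempt_records(out)
}

#' Write attempt-level records to CSV
#'
#' Inverse of [read_attempts()]: absent values are written as `"-"` so that a
#' write-then-read round trip reproduces the records field for field.
#'
#' @param records An `"attempt_records"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attempts <- function(records, path) {
  records <- as.data.frame(records)
  fmt <- function(x) ifelse(is.na(x), "-", format(x, scientific = FALSE,
                                                  trim = TRUE))
  out <- data.frame(
    attempt = fmt(records$attempt),
    date = ifelse(is.na(records$date), "-",
                  format(records$date, "%Y-%m-%d")),
    stage1_mistakes = fmt(records$stage1_mistakes),
    stage2_mistakes = fmt(records$stage2_mistakes),
    stage3_mistakes = fmt(records$stage3_mistakes),
    total_score = fmt(records$total_score),
    stage1_time = fmt(records$stage1_time),
    stage2_time = fmt(records$stage2_time),
    stage3_time = fmt(records$stage3_time),
    total_time = fmt(records$total_time),
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate attempt-level records
#'
#' Checks the structural invariants of an attempt-record set and reports
#' every violation without raising or mutating anything. In `"strict"` mode
#' the per-stage mistake scores must sum to the printed total score; in
#' `"lenient"` mode the total score is treated as authoritative (raw archival
#' tables are known to contain rows where the two disagree) and only timing
#' consistency and attempt-index contiguity are checked.
#'
#' Issue codes: `score_sum` (stage mistake scores inconsistent with
#' `total_score`), `time_sum` (stage times inconsistent with `total_time`),
#' `noncontiguous` (attempt indices not running 1..n without gaps or
#' duplicates).
#'
#' @param records An `"attempt_records"` data frame (non-empty).
#' @param mode `"strict"` or `"lenient"`.
#' @return An object of class `"validation_report"`: a list with `n_records`,
#'   an `issues` data frame (`attempt`, `code`, `message`), and `is_clean`.
#' @examples
#' rec <- read_attempts(system.file("extdata", "anastomosis_sample.csv",
#'                                  package = "lcgate"))
#' validate_attempts(rec, mode = "strict")
#' @export
validate_attempts <- function(records, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("'records' must be non-empty")
  issues <- list()
  add <- function(attempt, code, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      attempt = attempt, code = code, message = message
    )
  }

  # contiguity: sorted attempt indices must be exactly 1..n
  idx <- sort(records$attempt)
  expected <- seq_len(nrow(records))
  if (!identical(as.integer(idx), expected)) {
    offenders <- setdiff(idx, expected)
    if (length(offenders) == 0L) offenders <- idx[duplicated(idx)]
    for (a in unique(offenders))
      add(a, "noncontiguous",
          sprintf("attempt indices are not contiguous from 1 (index %d)", a))
  }

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (mode == "strict") {
      stages <- c(r$stage1_mistakes, r$stage2_mistakes, r$stage3_mistakes)
      ssum <- sum(stages, na.rm = TRUE)
      if (!is.na(r$total_score) && ssum != r$total_score)
        add(r$attempt, "score_sum",
            sprintf("stage mistake scores sum to %d but total_score is %d",
                    ssum, r$total_score))
    }
    times <- c(r$stage1_time, r$stage2_time, r$stage3_time)
    if (!anyNA(times)) {
      if (!is.na(r$total_time) && sum(times) != r$total_time)
        add(r$attempt, "time_sum",
            sprintf("stage times sum to %d but total_time is %d",
                    sum(times), r$total_time))
    } else if (any(!is.na(times)) && !is.na(r$total_time) &&
               sum(times, na.rm = TRUE) > r$total_time) {
      add(r$attempt, "time_sum",
          "present stage times exceed total_time")
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(attempt = integer(), code = character(), message = character())
  structure(
    list(n_records = nrow(records), issues = issues,
         is_clean = nrow(issues) == 0L, mode = mode),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation (%s mode): %d record(s), %d issue(s)%s\n",
              x$mode, x$n_records, nrow(x$issues),
              if (x$is_clean) " - clean" else ""))
  if (!x$is_clean) print(x$issues, row.names = FALSE)
  invisible(x)
}

#' Classify attempts as major-mistake attempts
#'
#' An attempt counts as a major-mistake attempt when its total mistake score
#' reaches the rubric's major threshold (default: score >= 5).
#'
#' @param x An `"attempt_records"` data frame, or a numeric vector of total
#'   mistake scores.
#' @param rubric A [mistake_rubric()].
#' @return A logical vector, one element per attempt.
#' @examples
#' is_major(c(0, 4, 5, 9))
#' @export
is_major <- function(x, rubric = mistake_rubric()) {
  score <- if (is.data.frame(x)) x$total_score else x
  if (anyNA(score))
    stop("total_score must be present for every attempt")
  score >= rubric$major_threshold
}
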
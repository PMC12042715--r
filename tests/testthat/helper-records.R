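# Shared fixtures built in code.

sample_csv_path <- function() {
  system.file("extdata", "anastomosis_sample.csv", package = "lcgate")
}

sample_records <- function() read_attempts(sample_csv_path())

# A minimal consistent record set with the given major-mistake attempts.
make_records <- function(n, majors = integer(), time_base = 1500L) {
  score <- integer(n)
  score[majors] <- 5L
  tt <- rep(time_base, n)
  tt[majors] <- 0L
  s1 <- as.integer(round(tt * 0.25))
  s2 <- as.integer(round(tt * 0.25))
  s3 <- tt - s1 - s2
  s1[majors] <- NA_integer_; s2[majors] <- NA_integer_
  s3[majors] <- NA_integer_
  df <- data.frame(
    attempt = seq_len(n), date = as.Date(NA),
    stage1_mistakes = NA_integer_,
    stage2_mistakes = ifelse(score == 5L, 5L, NA_integer_),
    stage3_mistakes = NA_integer_,
    total_score = score,
    stage1_time = s1, stage2_time = s2, stage3_time = s3,
    total_time = tt
  )
  class(df) <- c("attempt_records", "data.frame")
  df
}

# 0/1 indicator vector with ones at the given positions.
make_indicators <- function(n, majors) {
  ind <- integer(n)
  ind[majors] <- 1L
  ind
}

# Run the CLI in-process, swallowing logs and printed summaries.
run_cli <- function(args) {
  code <- NULL
  utils::capture.output(
    code <- suppressWarnings(suppressMessages(lcgate_main(args))))
  code
}
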
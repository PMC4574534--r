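#' Read and write segment score sheets
#'
#' CSV interchange: one row per segment per read, columns `participant_id`,
#' `read_id`, `segment_id`, `diagnostic` (0/1), `grade` (0--4, empty for
#' non-diagnostic segments).
#'
#' @param path CSV path.
#' @param scores Long score data.frame.
#' @return `read_segment_scores()` returns the data.frame;
#'   `write_segment_scores()` returns `path` invisibly.
#' @export
read_segment_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "read_id", "segment_id", "diagnostic",
              "grade")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("score sheet missing columns: ", paste(miss, collapse = ", "))
  }
  df$segment_id <- as.integer(df$segment_id)
  df$diagnostic <- as.integer(df$diagnostic)
  df$grade <- suppressWarnings(as.integer(df$grade))
  df
}

#' @rdname read_segment_scores
#' @export
write_segment_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write the demographics table
#'
#' CSV with one row per participant; required columns are `participant_id`
#' and `group`, with the usual clinical fields (`age`, `sex`, `height_cm`,
#' `weight_kg`, `bmi`, `hypertension`, `smoker`, `hba1c`, `lge`, prior-event
#' flags) as available.
#'
#' @param path CSV path.
#' @param demographics Data.frame.
#' @return `read_demographics()` returns the data.frame.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "group"), names(df))
  if (length(miss)) {
    stop("demographics missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_demographics
#' @export
write_demographics <- function(demographics, path) {
  utils::write.csv(demographics, path, row.names = FALSE, na = "")
  invisible(path)
}
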
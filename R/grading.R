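#' Categorical stenosis grade from a percent stenosis
#'
#' Maps a luminal narrowing, expressed as percent diameter stenosis, to the
#' five-level categorical grade used for whole-body angiographic scoring:
#'
#' * grade 0 -- no stenosis (exactly 0 %)
#' * grade 1 -- stenosis below 50 %
#' * grade 2 -- 50 to <70 % stenosis
#' * grade 3 -- 70 to <100 % stenosis
#' * grade 4 -- complete occlusion (exactly 100 %)
#'
#' Bins are half-open, so the 50 % and 70 % boundaries belong to the higher
#' grade. A vessel is graded at its narrowest point; see [score_vessel()] for
#' the multi-lesion rule.
#'
#' @param stenosis_percent Numeric vector of percent stenosis in \[0, 100\].
#' @return Integer vector of grades 0--4.
#' @examples
#' grade_from_stenosis(c(0, 30, 50, 60, 99, 100))
#' @export
grade_from_stenosis <- function(stenosis_percent) {
  x <- as.numeric(stenosis_percent)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    stop("stenosis_percent must be finite and within [0, 100]")
  }
  g <- integer(length(x))
  g[x > 0] <- 1L
  g[x >= 50] <- 2L
  g[x >= 70] <- 3L
  g[x == 100] <- 4L
  g
}

#' Grade a vessel segment carrying one or more stenoses
#'
#' Where a segment has several lesions, the most severe stenosis determines
#' the segment's grade.
#'
#' @param stenoses Non-empty numeric vector of percent stenoses in \[0, 100\].
#' @return A single integer grade 0--4.
#' @examples
#' score_vessel(c(10, 80, 30))  # graded on the 80 % lesion -> 3
#' @export
score_vessel <- function(stenoses) {
  if (length(stenoses) == 0L) {
    stop("at least one stenosis value is required to grade a vessel")
  }
  grade_from_stenosis(max(as.numeric(stenoses)))
}

#' Stenosis grade definitions
#'
#' The five categorical grades together with the half-open percent-stenosis
#' interval each one covers. Useful for report labelling and for sampling a
#' percent consistent with a grade.
#'
#' @return A data.frame with columns `grade`, `lower`, `upper`, `label`.
#'   `lower` is inclusive and `upper` exclusive except for the point grades
#'   0 and 4.
#' @export
stenosis_grades <- function() {
  data.frame(
    grade = 0:4,
    lower = c(0, 0, 50, 70, 100),
    upper = c(0, 50, 70, 100, 100),
    label = c(
      "no stenosis", "<50 % stenosis", "50-70 % stenosis",
      "70-99 % stenosis", "occlusion"
    ),
    stringsAsFactors = FALSE
  )
}
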
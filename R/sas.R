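#' Standardised atheroma score (SAS)
#'
#' The SAS condenses a participant's per-segment stenosis grades into a single
#' burden score on a 0--100 scale: the grades of the diagnostic segments are
#' summed, divided by the number of diagnostic segments `n`, divided by the
#' maximum grade 4, and multiplied by 100,
#' \deqn{SAS = \left[\left(\frac{\sum grade}{n}\right) \div 4\right] \times 100.}
#' Non-diagnostic segments are excluded from both numerator and denominator.
#' With no diagnostic segment at all the score is undefined: `NA` is returned
#' with a warning, never 0, so that undefined scores can be excluded from
#' group statistics rather than biasing them.
#'
#' @param scores A data.frame of one participant's (one read's) segment scores
#'   with columns `segment_id`, `diagnostic` (logical or 0/1) and `grade`
#'   (integer 0--4, `NA` for non-diagnostic segments).
#' @return A single numeric score in \[0, 100\], or `NA` if no segment is
#'   diagnostic.
#' @examples
#' s <- data.frame(segment_id = 1:31, diagnostic = TRUE,
#'                 grade = c(4, 3, 2, 1, rep(0, 27)))
#' compute_sas(s)  # 8.06
#' @seealso [compute_regional_sas()], [score_cohort()]
#' @export
compute_sas <- function(scores) {
  scores <- validate_segment_scores(scores)
  n <- sum(scores$diagnostic)
  if (n == 0L) {
    warning("SAS undefined: no diagnostic segments", call. = FALSE)
    return(NA_real_)
  }
  (sum(scores$grade[scores$diagnostic]) / n) / 4 * 100
}

#' Regional standardised atheroma scores
#'
#' Applies the SAS formula separately within each anatomical territory,
#' restricted to that territory's diagnostic segments. A territory with zero
#' diagnostic segments yields `NA` (undefined), silently.
#'
#' @inheritParams compute_sas
#' @param taxonomy Segment taxonomy mapping `segment_id` to territory;
#'   defaults to [wbmra_taxonomy()].
#' @return Named numeric vector of territory scores, in the order of
#'   [wbmra_territories()]. Territories with no scored segment are `NA`.
#' @export
compute_regional_sas <- function(scores, taxonomy = wbmra_taxonomy()) {
  scores <- validate_segment_scores(scores)
  validate_taxonomy(taxonomy)
  unknown <- setdiff(scores$segment_id, taxonomy$segment_id)
  if (length(unknown)) {
    stop("segment_id not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  terr <- taxonomy$territory[match(scores$segment_id, taxonomy$segment_id)]
  vapply(wbmra_territories(), function(tt) {
    sub <- scores[terr == tt, , drop = FALSE]
    if (nrow(sub) == 0L || sum(sub$diagnostic) == 0L) return(NA_real_)
    (sum(sub$grade[sub$diagnostic]) / sum(sub$diagnostic)) / 4 * 100
  }, numeric(1))
}

#' Atheroma profile for one participant and read
#'
#' Bundles a participant's 31 segment scores with the derived whole-body and
#' territory SAS values.
#'
#' @inheritParams compute_regional_sas
#' @return An object of class `atheroma_profile`: a list with elements
#'   `participant_id`, `read_id`, `scores`, `n_diagnostic`, `wb_sas` and
#'   `territory_sas`.
#' @export
atheroma_profile <- function(scores, taxonomy = wbmra_taxonomy()) {
  scores <- validate_segment_scores(scores)
  wb <- suppressWarnings(compute_sas(scores))
  structure(
    list(
      participant_id = if ("participant_id" %in% names(scores))
        unique(scores$participant_id) else NA_character_,
      read_id = if ("read_id" %in% names(scores))
        unique(scores$read_id) else NA_character_,
      scores = scores,
      n_diagnostic = sum(scores$diagnostic),
      wb_sas = wb,
      territory_sas = compute_regional_sas(scores, taxonomy)
    ),
    class = "atheroma_profile"
  )
}

#' @export
print.atheroma_profile <- function(x, ...) {
  cat("Atheroma profile:", x$participant_id,
      if (!is.na(x$read_id)) paste0("(read ", x$read_id, ")"), "\n")
  cat(sprintf("  diagnostic segments: %d / %d\n",
              x$n_diagnostic, nrow(x$scores)))
  cat(sprintf("  whole-body SAS: %s\n",
              if (is.na(x$wb_sas)) "undefined" else sprintf("%.1f", x$wb_sas)))
  ts <- x$territory_sas
  cat("  territory SAS:",
      paste(sprintf("%s=%s", names(ts),
                    ifelse(is.na(ts), "NA", sprintf("%.1f", ts))),
            collapse = ", "), "\n")
  invisible(x)
}

# Shared score-sheet validation: one participant/read, no duplicate segments,
# grade present exactly for diagnostic segments, grades in 0-4.
validate_segment_scores <- function(scores) {
  stopifnot(is.data.frame(scores))
  needed <- c("segment_id", "diagnostic", "grade")
  miss <- setdiff(needed, names(scores))
  if (length(miss)) {
    stop("segment scores missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(scores$segment_id)) {
    dup <- unique(scores$segment_id[duplicated(scores$segment_id)])
    stop("duplicate segment_id in scores: ", paste(dup, collapse = ", "))
  }
  for (col in intersect(c("participant_id", "read_id"), names(scores))) {
    if (length(unique(scores[[col]])) > 1L) {
      stop("scores must come from a single ", col,
           "; got ", length(unique(scores[[col]])))
    }
  }
  scores$diagnostic <- as.logical(scores$diagnostic)
  if (anyNA(scores$diagnostic)) stop("diagnostic flag must be 0/1 or logical")
  g <- scores$grade
  if (any(scores$diagnostic & is.na(g))) {
    stop("diagnostic segments must carry a grade")
  }
  if (any(!scores$diagnostic & !is.na(g))) {
    stop("non-diagnostic segments must not carry a grade")
  }
  gd <- g[!is.na(g)]
  if (length(gd) && (any(gd != round(gd)) || any(gd < 0) || any(gd > 4))) {
    stop("grades must be integers in 0-4")
  }
  scores
}

#' Score a whole cohort of segment sheets
#'
#' Computes the whole-body and territory SAS for every participant/read
#' combination present in a long score table.
#'
#' @param scores Long data.frame with columns `participant_id`, `read_id`,
#'   `segment_id`, `diagnostic`, `grade` (one row per segment per read).
#' @param taxonomy Segment taxonomy; defaults to [wbmra_taxonomy()].
#' @return A data.frame with one row per participant x read: `participant_id`,
#'   `read_id`, `n_diagnostic`, `wb_sas` and one `sas_<territory>` column per
#'   territory. Undefined scores are `NA`.
#' @export
score_cohort <- function(scores, taxonomy = wbmra_taxonomy()) {
  stopifnot(is.data.frame(scores))
  if (!"read_id" %in% names(scores)) scores$read_id <- "R1"
  key <- interaction(scores$participant_id, scores$read_id, drop = TRUE)
  parts <- split(scores, key)
  rows <- lapply(parts, function(sub) {
    wb <- suppressWarnings(compute_sas(sub))
    ts <- compute_regional_sas(sub, taxonomy)
    out <- data.frame(
      participant_id = sub$participant_id[1], read_id = sub$read_id[1],
      n_diagnostic = sum(as.logical(sub$diagnostic)), wb_sas = wb,
      stringsAsFactors = FALSE
    )
    out[paste0("sas_", names(ts))] <- as.list(unname(ts))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$participant_id, res$read_id), , drop = FALSE]
}

#' Segment-count summary over a cohort
#'
#' Tabulates, overall and per group, the counts a whole-body angiographic
#' results section reports: diagnostic and non-diagnostic segments, segments
#' per grade, segments with any luminal narrowing (grade > 0) and occlusions,
#' plus participant-level prevalence of any stenosis and of >50 % stenosis
#' (grade >= 2) in any vessel.
#'
#' Percentages are reported exactly (one decimal place is applied only by the
#' report writer), with segment percentages taken over diagnostic segments.
#'
#' @param scores Long cohort score table (one read), as in [score_cohort()].
#' @param group Optional grouping: either a data.frame with columns
#'   `participant_id` and `group`, or a named vector mapping participant to
#'   group label.
#' @return A data.frame with one row per group plus an `"overall"` row.
#' @export
summarize_segment_counts <- function(scores, group = NULL) {
  stopifnot(is.data.frame(scores))
  if (!"read_id" %in% names(scores)) scores$read_id <- "R1"
  if (length(unique(scores$read_id)) > 1L) {
    stop("summarize_segment_counts expects a single read; filter read_id first")
  }
  if (is.null(group)) {
    grp <- rep("all", nrow(scores))
  } else if (is.data.frame(group)) {
    grp <- as.character(group$group[match(scores$participant_id,
                                          group$participant_id)])
  } else {
    grp <- as.character(group[as.character(scores$participant_id)])
  }
  if (anyNA(grp)) stop("group label missing for some participants")

  one_block <- function(sub, label) {
    diag <- as.logical(sub$diagnostic)
    g <- sub$grade
    per_part <- split(g[diag], sub$participant_id[diag])
    any_sten <- vapply(per_part, function(v) any(v > 0), logical(1))
    any_gt50 <- vapply(per_part, function(v) any(v >= 2), logical(1))
    n_part <- length(unique(sub$participant_id))
    n_diag <- sum(diag)
    gr <- vapply(0:4, function(k) sum(g[diag] == k), integer(1))
    n_abn <- sum(gr[2:5])
    data.frame(
      group = label, n_participants = n_part, n_segments = nrow(sub),
      n_diagnostic = n_diag, n_nondiagnostic = sum(!diag),
      diagnostic_rate = 100 * n_diag / nrow(sub),
      grade0 = gr[1], grade1 = gr[2], grade2 = gr[3], grade3 = gr[4],
      grade4 = gr[5],
      n_abnormal = n_abn,
      pct_abnormal = 100 * n_abn / n_diag,
      pct_grade1 = 100 * gr[2] / n_diag,
      pct_grade2 = 100 * gr[3] / n_diag,
      pct_grade3 = 100 * gr[4] / n_diag,
      pct_occluded = 100 * gr[5] / n_diag,
      abnormal_per_participant = n_abn / n_part,
      n_any_stenosis = sum(any_sten),
      pct_any_stenosis = 100 * sum(any_sten) / n_part,
      n_gt50_any_vessel = sum(any_gt50),
      pct_gt50_any_vessel = 100 * sum(any_gt50) / n_part,
      stringsAsFactors = FALSE
    )
  }

  blocks <- lapply(sort(unique(grp)), function(gl) {
    one_block(scores[grp == gl, , drop = FALSE], gl)
  })
  res <- rbind(one_block(scores, "overall"), do.call(rbind, blocks))
  rownames(res) <- NULL
  res
}
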
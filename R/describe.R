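#' Normality-gated descriptive summary
#'
#' Summarises a variable the way a clinical cohort table does: mean +/- SD
#' when a Shapiro-Wilk test does not reject normality at `alpha`, otherwise
#' median with dispersion. Both dispersion conventions are computed — the
#' interquartile range and the min--max range — with the range as the default
#' display. All statistics are returned regardless of which branch is chosen,
#' so a forced scale only changes the label.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param forced_scale Optional `"parametric"` or `"nonparametric"` to bypass
#'   the normality gate.
#' @param alpha Significance level of the Shapiro-Wilk gate (default 0.05).
#' @return An object of class `cohort_summary`: list with `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `min`, `max`, `shapiro_p`, `scale` and a formatted
#'   `label`.
#' @export
describe <- function(values, forced_scale = NULL, alpha = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("describe needs at least 2 finite values")
  sw_p <- shapiro_p(x)
  scale <- if (!is.null(forced_scale)) {
    match.arg(forced_scale, c("parametric", "nonparametric"))
  } else if (is.na(sw_p) || sw_p >= alpha) {
    "parametric"
  } else {
    "nonparametric"
  }
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  out <- list(
    n = length(x), mean = mean(x), sd = stats::sd(x),
    median = stats::median(x), q1 = qs[1], q3 = qs[2],
    min = min(x), max = max(x), shapiro_p = sw_p, scale = scale
  )
  out$label <- if (scale == "parametric") {
    sprintf("%.1f ± %.1f", out$mean, out$sd)
  } else {
    sprintf("%.1f (%.1f–%.1f)", out$median, out$min, out$max)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s  [n=%d, %s; Shapiro-Wilk p=%s]\n", x$label, x$n, x$scale,
              if (is.na(x$shapiro_p)) "NA" else format.pval(x$shapiro_p)))
  invisible(x)
}

# Shapiro-Wilk p, robust to degenerate inputs. Returns NA when the test
# cannot run (n < 3, constant data); callers treat NA as "gate undecidable"
# and fall back to the parametric branch. Samples are capped at 5000 (the
# test's limit) by deterministic thinning.
shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  if (length(x) > 5000L) {
    x <- x[seq(1L, length(x), length.out = 5000L)]
  }
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' Transform ladder towards normality
#'
#' Tries, in order: identity, square root, logarithm, reciprocal — skipping
#' any transform undefined for the data's sign — and returns the first whose
#' transformed values pass a Shapiro-Wilk test at `alpha`. If none passes the
#' original values are returned tagged `"none_passed"`.
#'
#' @param values Finite numeric vector.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return List with `values` (transformed), `transform` (one of
#'   `"identity"`, `"sqrt"`, `"log"`, `"reciprocal"`, `"none_passed"`) and
#'   `shapiro_p` of the returned values.
#' @export
normalize_transform <- function(values, alpha = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) stop("no finite values")
  ladder <- list(
    identity = list(ok = function(v) TRUE, f = identity),
    sqrt = list(ok = function(v) all(v >= 0), f = sqrt),
    log = list(ok = function(v) all(v > 0), f = log),
    reciprocal = list(ok = function(v) all(v != 0), f = function(v) 1 / v)
  )
  for (tag in names(ladder)) {
    step <- ladder[[tag]]
    if (!step$ok(x)) next
    tx <- step$f(x)
    p <- shapiro_p(tx)
    if (is.na(p) || p >= alpha) {
      return(list(values = tx, transform = tag, shapiro_p = p))
    }
  }
  list(values = x, transform = "none_passed", shapiro_p = shapiro_p(x))
}
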
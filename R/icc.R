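#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' The agreement statistic used for intra-observer reliability of repeated
#' scoring. Subjects and reads are both treated as random samples, and
#' systematic differences between reads count against agreement. From the
#' two-way mean squares (rows = subjects, columns = reads),
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{n} subjects and \eqn{k} reads. The confidence interval follows
#' the standard F-distribution construction with Satterthwaite degrees of
#' freedom; the p-value tests ICC = 0 via \eqn{F = MS_R/MS_E} on
#' \eqn{(n-1, (n-1)(k-1))} degrees of freedom.
#'
#' @param ratings Numeric matrix, subjects in rows and reads in columns;
#'   at least 5 subjects, 2 reads, no missing cells (no imputation is done).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `agreement_result`: list with `icc`, `lower`,
#'   `upper`, `p_value`, `model` (`"ICC(2,1) absolute agreement"`), `n`, `k`
#'   and the mean squares `msr`, `msc`, `mse`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(10, 50, 10)
#' m <- cbind(truth + rnorm(10, 0, 2), truth + rnorm(10, 0, 2))
#' icc_2_1(m)
#' @export
icc_2_1 <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) stop("ratings must be numeric")
  if (anyNA(m)) stop("missing cells in ratings matrix; no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 reads")

  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  eps <- 1e-12 * max(abs(m), 1)
  if (denom <= eps^2) {
    # no variance anywhere: agreement is undefined
    stop("ratings have no variance; ICC undefined")
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf
  if (mse <= eps^2 && msc <= eps^2) {
    # identical columns: perfect agreement, degenerate F construction
    lower <- upper <- 1
    p <- 0
  } else {
    fv <- msr / mse
    p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    lower <- max(-1, min(lower, icc))
    upper <- min(1, max(upper, icc))
  }

  structure(
    list(icc = icc, lower = lower, upper = upper, p_value = p,
         model = "ICC(2,1) absolute agreement", conf = conf,
         n = n, k = k, msr = msr, msc = msc, mse = mse),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s\n", x$model))
  cat(sprintf("  ICC = %.3f (%d%% CI %.3f-%.3f), p %s  [n=%d subjects, k=%d reads]\n",
              x$icc, round(100 * x$conf), x$lower, x$upper,
              format.pval(x$p_value, digits = 3, eps = 1e-3), x$n, x$k))
  invisible(x)
}
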
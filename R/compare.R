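#' Four-group comparison with normality-gated test selection
#'
#' Compares a variable across study groups the way the cohort tables do:
#' one-way ANOVA with Bonferroni-corrected pairwise t contrasts when the data
#' (after the [normalize_transform()] ladder) pass the normality gate,
#' otherwise Kruskal-Wallis with Bonferroni-corrected pairwise rank-sum
#' contrasts. The Bonferroni family is all pairwise contrasts among the
#' groups (6 for four groups).
#'
#' Per-group descriptive summaries are always reported on the original scale;
#' only the test runs on the transformed values.
#'
#' @param values Numeric vector of observations.
#' @param group Group labels (coerced to factor), same length as `values`.
#' @param paradigm `"auto"` (gate on normality after the transform ladder),
#'   `"parametric"` or `"nonparametric"`.
#' @param variable Optional variable name carried into the result.
#' @param alpha Significance level used for the gate and the significance
#'   flags (default 0.05).
#' @return An object of class `group_comparison`: list with `variable`,
#'   `test` (`"anova"` or `"kruskal_wallis"`), `transform`, `omnibus_p`,
#'   `pairwise` (matrix of Bonferroni-adjusted p-values), `summaries` (named
#'   list of [describe()] results) and `groups`.
#' @export
compare_groups <- function(values, group,
                           paradigm = c("auto", "parametric", "nonparametric"),
                           variable = NULL, alpha = 0.05) {
  paradigm <- match.arg(paradigm)
  stopifnot(length(values) == length(group))
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- factor(group[keep])
  sizes <- table(group)
  if (any(sizes < 2L)) {
    small <- names(sizes)[sizes < 2L]
    warning("excluding groups with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !(group %in% small)
    values <- values[keep]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups with n >= 2")

  transform <- "identity"
  test_values <- values
  if (paradigm == "auto") {
    tr <- normalize_transform(values, alpha = alpha)
    if (tr$transform == "none_passed") {
      paradigm <- "nonparametric"
    } else {
      paradigm <- "parametric"
      transform <- tr$transform
      test_values <- tr$values
    }
  }

  if (paradigm == "parametric") {
    fit <- stats::aov(test_values ~ group)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(test_values, group,
                                 p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)$p.value
    test <- "anova"
  } else {
    omnibus_p <- stats::kruskal.test(values, group)$p.value
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, group,
                                  p.adjust.method = "bonferroni",
                                  exact = FALSE)$p.value
    )
    test <- "kruskal_wallis"
    transform <- "identity"
  }

  summaries <- lapply(split(values, group), describe, alpha = alpha)
  structure(
    list(
      variable = variable %||% "value", test = test, transform = transform,
      omnibus_p = omnibus_p, pairwise = pw, summaries = summaries,
      groups = levels(group), alpha = alpha
    ),
    class = "group_comparison"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted-p lookup in a pairwise comparison matrix
#'
#' @param x A `group_comparison`.
#' @param g1,g2 Group labels.
#' @return The Bonferroni-adjusted p-value for that contrast.
#' @export
pairwise_p <- function(x, g1, g2) {
  stopifnot(inherits(x, "group_comparison"))
  pw <- x$pairwise
  if (g1 %in% rownames(pw) && g2 %in% colnames(pw) && !is.na(pw[g1, g2])) {
    return(pw[g1, g2])
  }
  if (g2 %in% rownames(pw) && g1 %in% colnames(pw) && !is.na(pw[g2, g1])) {
    return(pw[g2, g1])
  }
  NA_real_
}

#' Significance markers against the reference groups
#'
#' Reproduces the footnote convention of the comparison tables: for each
#' group, `"*"` when its Bonferroni-adjusted contrast against the disease-free
#' reference (default group `"2"`) is significant, `"**"` when significant
#' against both reference groups (defaults `"2"` and `"4"`), and `"^"` when
#' significant against the healthy controls (`"4"`) only.
#'
#' @param x A `group_comparison`.
#' @param ref_a,ref_b The two reference groups.
#' @return Named character vector of markers per group.
#' @export
significance_markers <- function(x, ref_a = "2", ref_b = "4") {
  stopifnot(inherits(x, "group_comparison"))
  vapply(x$groups, function(g) {
    if (g %in% c(ref_a, ref_b)) return("")
    pa <- pairwise_p(x, g, ref_a)
    pb <- pairwise_p(x, g, ref_b)
    sa <- !is.na(pa) && pa < x$alpha
    sb <- !is.na(pb) && pb < x$alpha
    if (sa && sb) "**" else if (sa) "*" else if (sb) "^" else ""
  }, character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (%s%s)\n", x$variable,
              if (x$test == "anova") "one-way ANOVA" else "Kruskal-Wallis",
              if (x$transform != "identity")
                paste0(", ", x$transform, "-transformed") else ""))
  for (g in x$groups) {
    cat(sprintf("  group %s: %s\n", g, x$summaries[[g]]$label))
  }
  cat(sprintf("  omnibus p = %s\n", format.pval(x$omnibus_p, digits = 3)))
  invisible(x)
}
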
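test_that("describe gates between mean±SD and median(range) on normality", {
  const <- rep(5, 10)
  d <- describe(const)
  expect_equal(d$sd, 0)
  expect_equal(d$median, 5)
  set.seed(41)
  norm <- rnorm(500)
  expect_equal(describe(norm)$scale, "parametric")
  set.seed(42)
  expo <- rexp(500)
  d2 <- describe(expo)
  expect_equal(d2$scale, "nonparametric")
  # both dispersion conventions are always available
  expect_true(all(c("q1", "q3", "min", "max") %in% names(d2)))
  expect_equal(describe(expo, forced_scale = "parametric")$scale,
               "parametric")
  expect_error(describe(1), "at least 2")
})

test_that("the transform ladder tries identity, sqrt, log, reciprocal in order", {
  set.seed(7)
  ln <- exp(rnorm(300, 1, 0.8))
  r <- normalize_transform(ln)
  expect_equal(r$transform, "log")
  expect_equal(r$values, log(ln))
  set.seed(8)
  expect_equal(normalize_transform(rnorm(300))$transform, "identity")
  # all-negative data: sqrt and log are skipped by the domain rule
  set.seed(9)
  neg <- -exp(rnorm(300, 1, 0.8))
  rn <- normalize_transform(neg)
  expect_true(rn$transform %in% c("reciprocal", "none_passed"))
})

test_that("group comparison: trivial null, large shift, and paradigm selection", {
  g <- rep(1:4, each = 20)
  same <- rep(sin(1:20) * 2 + 5, 4)  # identical groups
  cmp <- compare_groups(same, g)
  expect_gt(cmp$omnibus_p, 0.5)
  set.seed(13)
  x <- c(rnorm(50, 0, 1), rnorm(50, 3, 1))
  cmp2 <- compare_groups(x, rep(1:2, each = 50))
  expect_lt(cmp2$omnibus_p, 0.001)
  # forcing the parametric paradigm gives the ANOVA route explicitly
  cmp2p <- compare_groups(x, rep(1:2, each = 50), paradigm = "parametric")
  expect_equal(cmp2p$test, "anova")
  expect_lt(cmp2p$omnibus_p, 0.001)
  # heavy-tailed data that no ladder step normalises -> rank test
  set.seed(14)
  h <- rcauchy(120)
  cmp3 <- compare_groups(h, rep(1:4, each = 30))
  expect_equal(cmp3$test, "kruskal_wallis")
})

test_that("two-group ANOVA equals the pooled t-test; KW matches rank-sum brute force", {
  set.seed(15)
  x <- rnorm(60)
  g <- rep(1:2, each = 30)
  p_aov <- compare_groups(x, g, paradigm = "parametric")$omnibus_p
  p_t <- t.test(x ~ g, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t)
  # Kruskal-Wallis with two groups from explicit rank arithmetic
  r <- rank(x)
  n <- length(x); n1 <- sum(g == 1)
  H <- 12 / (n * (n + 1)) *
    (sum(r[g == 1])^2 / n1 + sum(r[g == 2])^2 / (n - n1)) - 3 * (n + 1)
  p_kw <- compare_groups(x, g, paradigm = "nonparametric")$omnibus_p
  expect_equal(p_kw, pchisq(H, df = 1, lower.tail = FALSE))
})

test_that("the Kruskal-Wallis branch is invariant to monotone transformation", {
  set.seed(16)
  x <- rexp(90)
  g <- rep(1:3, each = 30)
  p1 <- compare_groups(x, g, paradigm = "nonparametric")$omnibus_p
  p2 <- compare_groups(exp(x) + 5, g, paradigm = "nonparametric")$omnibus_p
  expect_equal(p1, p2)
})

test_that("groups with n < 2 are excluded with a warning", {
  x <- c(rnorm(20), 1)
  g <- c(rep(1:2, each = 10), 3)
  expect_warning(cmp <- compare_groups(x, g), "n < 2")
  expect_setequal(cmp$groups, c("1", "2"))
})

test_that("ANCOVA reduces to one-way ANOVA when covariates are constant", {
  set.seed(17)
  d <- ancova_sim(20, effect = c(4, 0, 2, 0))
  d$age <- 64; d$sex <- 1; d$bmi <- 29; d$hypertension <- 0; d$smoker <- 0
  expect_warning(a <- ancova_adjust(d, "y", pairwise = FALSE),
                 "constant covariates")
  p_anova <- summary(stats::aov(y ~ factor(group), data = d))[[1]][1, "Pr(>F)"]
  expect_equal(a$group_p, p_anova)
})

test_that("ANCOVA finds no group effect when a covariate explains the outcome", {
  set.seed(18)
  d <- ancova_sim(30, effect = c(0, 0, 0, 0), beta_age = 2, sd_resid = 2)
  # age differs by group, outcome tracks age only
  d$age <- d$age + c(5, 0, 3, -4)[d$group]
  d$y <- 50 + 2 * (d$age - 64) + rnorm(nrow(d), 0, 2)
  a <- ancova_adjust(d, "y", pairwise = FALSE)
  expect_gt(a$group_p, 0.05)
})

test_that("ANCOVA rejects rank-deficient designs naming the collinear column", {
  set.seed(19)
  d <- ancova_sim(15)
  d$bmi <- d$age * 2  # exact collinearity
  expect_error(ancova_adjust(d, "y"), "collinear.*bmi|bmi.*collinear")
})

test_that("ANCOVA pairwise contrasts are Bonferroni-adjusted adjusted-mean differences", {
  set.seed(27)
  d <- ancova_sim(40, effect = c(10, 0, 0, 0))
  a <- ancova_adjust(d, "y")
  expect_equal(nrow(a$contrasts), 6)
  r14 <- a$contrasts[grepl("group4.*group1|group1.*group4",
                           a$contrasts$contrast), ]
  expect_equal(nrow(r14), 1)
  expect_true(r14$p_bonferroni < 0.05)
})
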
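test_that("stenosis grading follows the categorical bins with half-open boundaries", {
  cases <- data.frame(
    pct = c(0, 0.1, 25, 49.9, 50, 60, 69.9, 70, 85, 99.9, 100),
    grade = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)
  )
  expect_identical(grade_from_stenosis(cases$pct), cases$grade)
  expect_error(grade_from_stenosis(-1), "0, 100")
  expect_error(grade_from_stenosis(101), "0, 100")
  expect_error(grade_from_stenosis(NA), "0, 100")
})

test_that("a multi-lesion vessel is graded on its most severe stenosis", {
  expect_identical(score_vessel(c(10, 80, 30)), 3L)
  expect_identical(score_vessel(c(0, 0)), 0L)
  expect_identical(score_vessel(100), 4L)
  expect_error(score_vessel(numeric(0)), "at least one")
})

test_that("SAS evaluates the standardised formula on hand-worked sheets", {
  all0 <- data.frame(segment_id = 1:31, diagnostic = TRUE, grade = 0L)
  expect_equal(compute_sas(all0), 0)
  all4 <- data.frame(segment_id = 1:31, diagnostic = TRUE, grade = 4L)
  expect_equal(compute_sas(all4), 100)
  mixed <- data.frame(segment_id = 1:31, diagnostic = TRUE,
                      grade = c(4L, 3L, 2L, 1L, rep(0L, 27)))
  expect_equal(round(compute_sas(mixed), 2), 8.06)
  # only 4 diagnostic segments: denominator shrinks to 4
  sparse <- data.frame(segment_id = 1:31,
                       diagnostic = c(rep(TRUE, 4), rep(FALSE, 27)),
                       grade = c(4L, 3L, 2L, 1L, rep(NA, 27)))
  expect_equal(compute_sas(sparse), 62.5)
})

test_that("SAS is undefined (NA with warning), never zero, when no segment is diagnostic", {
  none <- data.frame(segment_id = 1:31, diagnostic = FALSE,
                     grade = NA_integer_)
  expect_warning(res <- compute_sas(none), "undefined")
  expect_true(is.na(res))
})

test_that("score sheets are validated: duplicates, grade/diagnostic consistency, range", {
  dup <- data.frame(segment_id = c(1, 1, 2), diagnostic = TRUE, grade = 0L)
  expect_error(compute_sas(dup), "duplicate segment_id")
  bad_flag <- data.frame(segment_id = 1:2, diagnostic = c(TRUE, FALSE),
                         grade = c(NA, 1L))
  expect_error(compute_sas(bad_flag), "must")
  bad_grade <- data.frame(segment_id = 1:2, diagnostic = TRUE,
                          grade = c(5L, 0L))
  expect_error(compute_sas(bad_grade), "0-4")
})

test_that("SAS respects bounds, permutation invariance and the flat-grade identity", {
  set.seed(101)
  for (i in 1:50) {
    prof <- random_profile()
    s <- suppressWarnings(compute_sas(prof))
    if (!is.na(s)) expect_true(s >= 0 && s <= 100)
    perm <- prof[sample(nrow(prof)), , drop = FALSE]
    expect_identical(suppressWarnings(compute_sas(perm)), s)
  }
  for (g in 0:4) {
    flat <- data.frame(segment_id = 1:31, diagnostic = TRUE, grade = g)
    expect_equal(compute_sas(flat), 100 * g / 4)
  }
})

test_that("marking extreme-grade segments non-diagnostic moves SAS monotonically", {
  set.seed(202)
  for (i in 1:25) {
    prof <- random_profile(p_nondx = 0)
    s0 <- compute_sas(prof)
    z <- which(prof$grade == 0L)
    if (length(z)) {
      p2 <- prof
      p2$diagnostic[z[1]] <- FALSE
      p2$grade[z[1]] <- NA_integer_
      expect_gte(compute_sas(p2), s0)
    }
    f <- which(prof$grade == 4L)
    if (length(f)) {
      p3 <- prof
      p3$diagnostic[f[1]] <- FALSE
      p3$grade[f[1]] <- NA_integer_
      expect_lte(compute_sas(p3), s0)
    }
  }
})

test_that("regional SAS applies the formula per territory and matches trivial patterns", {
  tax <- wbmra_taxonomy()
  all0 <- data.frame(segment_id = 1:31, diagnostic = TRUE, grade = 0L)
  expect_true(all(compute_regional_sas(all0) == 0))
  aorta_ids <- tax$segment_id[tax$territory == "aorta"]
  one <- all0
  one$grade[one$segment_id %in% aorta_ids] <- 4L
  reg <- compute_regional_sas(one)
  expect_equal(unname(reg["aorta"]), 100)
  expect_true(all(reg[setdiff(names(reg), "aorta")] == 0))
  unknown <- data.frame(segment_id = c(1, 99), diagnostic = TRUE, grade = 0L)
  expect_error(compute_regional_sas(unknown), "not in taxonomy")
})

test_that("whole-body SAS equals the diagnostic-count-weighted mean of territory SAS", {
  tax <- wbmra_taxonomy()
  terr <- tax$territory[order(tax$segment_id)]
  set.seed(303)
  for (i in 1:50) {
    prof <- random_profile()
    wb <- suppressWarnings(compute_sas(prof))
    reg <- compute_regional_sas(prof)
    w <- vapply(wbmra_territories(), function(tt) {
      sum(prof$diagnostic[terr == tt])
    }, numeric(1))
    if (sum(w) == 0) next
    keep <- w > 0
    expect_equal(wb, sum(reg[keep] * w[keep]) / sum(w))
  }
})

test_that("segment-count summary tallies grades, rates and participant prevalence", {
  one <- data.frame(participant_id = "A", read_id = "R1", segment_id = 1:31,
                    diagnostic = 1L, grade = 0L)
  s <- summarize_segment_counts(one)
  ov <- s[s$group == "overall", ]
  expect_equal(ov$n_abnormal, 0)
  expect_equal(ov$pct_any_stenosis, 0)
  expect_equal(ov$diagnostic_rate, 100)

  two <- rbind(one,
               transform(one, participant_id = "B",
                         grade = c(rep(2L, 3), rep(0L, 28))))
  grp <- data.frame(participant_id = c("A", "B"), group = c(4, 1))
  s2 <- summarize_segment_counts(two, group = grp)
  expect_setequal(s2$group, c("overall", "1", "4"))
  g1 <- s2[s2$group == "1", ]
  expect_equal(g1$grade2, 3)
  expect_equal(g1$pct_gt50_any_vessel, 100)
  expect_equal(s2[s2$group == "4", "pct_any_stenosis"], 0)
})

test_that("taxonomy round-trips through YAML and enforces its invariants", {
  tax <- wbmra_taxonomy()
  expect_equal(as.integer(table(tax$territory)[wbmra_territories()]),
               c(9L, 3L, 5L, 6L, 8L))
  tmp <- tempfile(fileext = ".yaml")
  write_taxonomy(tax, tmp)
  back <- read_taxonomy(tmp)
  expect_equal(back$territory, tax$territory)
  expect_equal(back$name, tax$name)
  bad <- tax
  bad$territory[1] <- "coronary"
  expect_error(validate_taxonomy(bad), "unknown territory")
  expect_error(validate_taxonomy(tax[-1, ]), "exactly segments 1-31")
})
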
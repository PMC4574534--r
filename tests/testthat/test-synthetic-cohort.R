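test_that("diabetes/CVD status maps to the four study groups bijectively", {
  expect_identical(assign_group(TRUE, TRUE), 1L)
  expect_identical(assign_group(TRUE, FALSE), 2L)
  expect_identical(assign_group(FALSE, TRUE), 3L)
  expect_identical(assign_group(FALSE, FALSE), 4L)
  combos <- expand.grid(t2dm = c(TRUE, FALSE), cvd = c(TRUE, FALSE))
  expect_setequal(assign_group(combos$t2dm, combos$cvd), 1:4)
})

test_that("configuration validation lists offending fields", {
  expect_error(cohort_config(n = c(10, 10)), "n must")
  expect_error(cohort_config(stenosis = list(p_abnormal = c(2, 0, 0, 0))),
               "p_abnormal")
  expect_error(
    cohort_config(stenosis = list(grade_probs = matrix(1, 4, 4))),
    "grade_probs")
  expect_error(cohort_config(noise = list(rescore_shift_p = 1.5)),
               "rescore_shift_p")
})

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(small_config(), seed = 77)
  b <- generate_cohort(small_config(), seed = 77)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$scores, b$scores)
  expect_identical(a$truth$lv, b$truth$lv)
  expect_identical(a$stacks[[1]]$ED$slices[[1]]$endo,
                   b$stacks[[1]]$ED$slices[[1]]$endo)
  c <- generate_cohort(small_config(), seed = 78)
  expect_false(identical(a$scores$grade, c$scores$grade))
})

test_that("zero abnormal-segment probability yields an all-zero SAS cohort", {
  cfg <- cohort_config(n = c(5L, 5L, 5L, 5L),
                       stenosis = list(p_abnormal = rep(0, 4)))
  co <- generate_cohort(cfg, seed = 3, contours = FALSE)
  sas <- score_cohort(co$scores)
  expect_true(all(sas$wb_sas == 0, na.rm = TRUE))
})

test_that("generated grades reproduce the configured abnormal prevalence within binomial CI", {
  # large single-group draw; frailty off so the marginal rate is the target
  cfg <- cohort_config(
    n = c(400L, 1L, 1L, 1L),
    stenosis = list(frailty_sdlog = rep(0, 4),
                    territory_mult = c(head_neck = 1, aorta = 1,
                                       abdominal = 1, iliofemoral = 1,
                                       runoff = 1))
  )
  co <- generate_cohort(cfg, seed = 31, contours = FALSE)
  sc <- co$scores[co$scores$participant_id %in%
                    co$demographics$participant_id[co$demographics$group == 1], ]
  diag <- sc$diagnostic == 1
  rate <- mean(sc$grade[diag] > 0)
  p0 <- cfg$stenosis$p_abnormal[1]
  n <- sum(diag)
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("true stenosis percents are consistent with the emitted grades", {
  co <- generate_cohort(small_config(), seed = 12, contours = FALSE)
  regraded <- grade_from_stenosis(as.vector(t(co$truth$grade * 0 +
                                                co$truth$stenosis_percent)))
  expect_identical(regraded, as.integer(as.vector(t(co$truth$grade))))
})

test_that("disc summation on generated stacks recovers analytic truth volumes", {
  cfg <- cohort_config(n = c(2L, 2L, 2L, 2L),
                       lv = list(slice_thickness = 2, gap = 0))
  co <- generate_cohort(cfg, seed = 8)
  for (i in seq_len(nrow(co$truth$lv))) {
    pid <- co$truth$lv$participant_id[i]
    edv <- simpson_volume(co$stacks[[pid]]$ED)
    esv <- simpson_volume(co$stacks[[pid]]$ES)
    expect_lt(abs(edv - co$truth$lv$edv_ml[i]) / co$truth$lv$edv_ml[i], 0.03)
    expect_lt(abs(esv - co$truth$lv$esv_ml[i]) / co$truth$lv$esv_ml[i], 0.03)
    lvm <- lv_mass(co$stacks[[pid]]$ED)
    expect_lt(abs(lvm - co$truth$lv$lvm_g[i]) / co$truth$lv$lvm_g[i], 0.05)
  }
})

test_that("default severity model orders group median SAS as 3 > 1 > 2 > 4", {
  cfg <- cohort_config(n = rep(500L, 4))
  ok <- vapply(1:20, function(r) {
    co <- generate_cohort(cfg, seed = 4000 + r, contours = FALSE)
    sas <- wbcvmr:::wb_sas_fast(co$scores)
    g <- co$demographics$group[match(names(sas),
                                     co$demographics$participant_id)]
    med <- tapply(sas, g, median, na.rm = TRUE)
    med["3"] > med["1"] && med["1"] > med["2"] && med["2"] > med["4"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noise-free rescoring is identity (ICC 1); noise strictly degrades agreement", {
  co <- generate_cohort(small_config(), seed = 9, contours = FALSE)
  r0 <- rescore_with_noise(co$scores, 0, seed = 1)
  expect_identical(r0$grade, co$scores$grade)
  expect_identical(r0$diagnostic, co$scores$diagnostic)
  sas1 <- wbcvmr:::wb_sas_fast(co$scores)
  expect_equal(icc_2_1(cbind(sas1, wbcvmr:::wb_sas_fast(r0)))$icc, 1)
  r1 <- rescore_with_noise(co$scores, 1, seed = 2)
  expect_identical(r1$diagnostic, co$scores$diagnostic)
  expect_true(all(abs(r1$grade - co$scores$grade) <= 1, na.rm = TRUE))
  icc_full <- icc_2_1(cbind(sas1, wbcvmr:::wb_sas_fast(r1)))$icc
  expect_lt(icc_full, 1)
})

test_that("LV metrics carry the configured group effect after covariate adjustment", {
  # single replicate of the recovery experiment (the acceptance run repeats it)
  co <- generate_cohort(cohort_config(), seed = 55, contours = FALSE)
  d <- co$demographics
  d$lvmi <- co$truth$lv$lvmi
  a <- ancova_adjust(d, "lvmi", pairwise = FALSE)
  est <- coef(a$model)["group1"]
  ci <- confint(a$model)["group1", ]
  truth <- co$truth$lv_group_effects[1]
  expect_true(ci[1] <= truth && truth <= ci[2])
  expect_lt(abs(est - truth), 10)
})
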
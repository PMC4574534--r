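# Shared fixture builders and independent oracles.

# Independent brute-force evaluation of the SAS definition: explicit loop,
# no shared code with compute_sas().
brute_sas <- function(scores) {
  total <- 0
  n <- 0
  for (i in seq_len(nrow(scores))) {
    if (isTRUE(as.logical(scores$diagnostic[i]))) {
      total <- total + scores$grade[i]
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  ((total / n) / 4) * 100
}

# Random single-participant score sheet (31 segments).
random_profile <- function(p_nondx = 0.05) {
  diag <- stats::runif(31) > p_nondx
  grade <- ifelse(diag, sample(0:4, 31, replace = TRUE,
                               prob = c(0.7, 0.15, 0.06, 0.05, 0.04)),
                  NA_integer_)
  data.frame(segment_id = 1:31, diagnostic = diag, grade = grade)
}

# Cohort-scale fixture reproducing the published segment-count arithmetic:
# 148 participants x 31 segments, 24 non-diagnostic segments spread over 6
# participants, per-grade abnormal counts 769/75/60/57 spread over exactly
# 135 participants (the rest all grade 0).
segment_count_fixture <- function() {
  n_part <- 148L
  pid <- sprintf("P%03d", 1:n_part)
  df <- data.frame(
    participant_id = rep(pid, each = 31L),
    read_id = "R1",
    segment_id = rep(1:31, times = n_part),
    diagnostic = 1L,
    grade = 0L,
    stringsAsFactors = FALSE
  )
  # 24 non-diagnostic segments in six examinations (4 each), chosen among
  # the 13 all-normal participants' rows so grades stay assignable
  nondx_parts <- pid[136:141]
  for (i in seq_along(nondx_parts)) {
    rows <- which(df$participant_id == nondx_parts[i])[1:4]
    df$diagnostic[rows] <- 0L
    df$grade[rows] <- NA_integer_
  }
  # abnormal grades over participants 1..135, round-robin so each of the
  # 135 gets at least one abnormal segment
  grades <- rep(c(1L, 2L, 3L, 4L), times = c(769L, 75L, 60L, 57L))
  abn_parts <- rep_len(1:135, length(grades))
  ord <- order(abn_parts)
  g_sorted <- grades[ord]
  p_sorted <- abn_parts[ord]
  seg_slot <- stats::ave(seq_along(p_sorted), p_sorted, FUN = seq_along)
  stopifnot(max(seg_slot) <= 31)
  rows <- (p_sorted - 1L) * 31L + seg_slot
  df$grade[rows] <- g_sorted
  df
}

# Demographics-like frame with a known group effect on a dependent variable.
ancova_sim <- function(n_per_group = 30, effect = c(0, 0, 0, 0),
                       beta_age = 0.5, beta_bmi = 0.8, sd_resid = 8) {
  n <- 4 * n_per_group
  g <- rep(1:4, each = n_per_group)
  age <- stats::rnorm(n, 64, 8)
  sex <- stats::rbinom(n, 1, 0.6)
  bmi <- stats::rnorm(n, 29, 4)
  htn <- stats::rbinom(n, 1, 0.6)
  smoker <- stats::rbinom(n, 1, 0.5)
  y <- 50 + effect[g] + beta_age * (age - 64) + beta_bmi * (bmi - 29) +
    3 * sex + stats::rnorm(n, 0, sd_resid)
  data.frame(y = y, group = g, age = age, sex = sex, bmi = bmi,
             hypertension = htn, smoker = smoker)
}

# Small, quick cohort configuration for pipeline-level tests.
small_config <- function() {
  cohort_config(n = c(10L, 12L, 8L, 8L))
}
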
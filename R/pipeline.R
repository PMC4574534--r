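#' Validate pipeline inputs
#'
#' Report-only structural validation of the three input artefacts: segment
#' score sheets, demographics and contour stacks. Checks segment-id coverage
#' against the taxonomy, grade ranges, diagnostic/grade consistency,
#' duplicate (participant, read, segment) rows, demographic completeness,
#' and contour polygon well-formedness (>= 3 vertices, simple, endocardial
#' area not exceeding epicardial).
#'
#' @param scores Long score data.frame, or `NULL`.
#' @param demographics Demographics data.frame, or `NULL`.
#' @param stacks Named list of contour stacks (per participant, `ED`/`ES`),
#'   or `NULL`.
#' @param taxonomy Segment taxonomy.
#' @return A data.frame of issues with columns `component`, `issue`, `ref`;
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(scores = NULL, demographics = NULL,
                            stacks = NULL, taxonomy = wbmra_taxonomy()) {
  issues <- list()
  add <- function(component, issue, ref = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      component = component, issue = issue, ref = as.character(ref),
      stringsAsFactors = FALSE)
  }

  if (!is.null(scores)) {
    if (!"read_id" %in% names(scores)) scores$read_id <- "R1"
    bad_seg <- which(!(scores$segment_id %in% taxonomy$segment_id))
    for (i in bad_seg) {
      add("scores", paste0("segment_id ", scores$segment_id[i],
                           " not in taxonomy"), paste0("row ", i))
    }
    g <- scores$grade
    bad_grade <- which(!is.na(g) & (g < 0 | g > 4 | g != round(g)))
    for (i in bad_grade) {
      add("scores", paste0("grade out of range 0-4: ", g[i]),
          paste0("row ", i))
    }
    diag <- as.logical(scores$diagnostic)
    incons <- which((diag & is.na(g)) | (!diag & !is.na(g)))
    for (i in incons) {
      add("scores", "diagnostic flag inconsistent with grade presence",
          paste0("row ", i))
    }
    key <- paste(scores$participant_id, scores$read_id, scores$segment_id)
    dup <- which(duplicated(key))
    for (i in dup) {
      add("scores", paste0("duplicate (participant, read, segment): ",
                           key[i]), paste0("row ", i))
    }
    cover <- tapply(scores$segment_id,
                    paste(scores$participant_id, scores$read_id),
                    function(s) length(unique(s)))
    for (k in names(cover)[cover < nrow(taxonomy)]) {
      add("scores", paste0("incomplete segment coverage (",
                           cover[[k]], "/", nrow(taxonomy), ")"), k)
    }
  }

  if (!is.null(demographics)) {
    needed <- c("participant_id", "group", "age", "sex", "height_cm",
                "weight_kg", "hypertension", "smoker")
    miss <- setdiff(needed, names(demographics))
    for (m in miss) add("demographics", paste0("missing column ", m))
    for (col in intersect(needed, names(demographics))) {
      nas <- which(is.na(demographics[[col]]))
      for (i in nas) {
        add("demographics", paste0("missing value in ", col),
            paste0("row ", i))
      }
    }
    if ("group" %in% names(demographics)) {
      bad <- which(!(demographics$group %in% 1:4))
      for (i in bad) {
        add("demographics", paste0("group not in 1-4: ",
                                   demographics$group[i]),
            paste0("row ", i))
      }
    }
  }

  if (!is.null(stacks)) {
    for (pid in names(stacks)) {
      for (ph in names(stacks[[pid]])) {
        st <- stacks[[pid]][[ph]]
        for (s in st$slices) {
          ref <- paste0(pid, "/", ph, "/slice ", s$index)
          for (surf in c("endo", "epi")) {
            poly <- s[[surf]]
            if (is.null(poly)) next
            if (nrow(poly) < 3L) {
              add("contours", paste0(surf, " polygon has <3 vertices"), ref)
            } else if (!is_simple_polygon(poly)) {
              add("contours", paste0(surf, " polygon self-intersects"), ref)
            }
          }
          if (!is.null(s$epi) &&
              polygon_area(s$epi) < polygon_area(s$endo) - 1e-9) {
            add("contours", "endocardial area exceeds epicardial", ref)
          }
        }
      }
    }
  }

  if (!length(issues)) {
    return(data.frame(component = character(), issue = character(),
                      ref = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

# Proper-crossing test over all non-adjacent edge pairs (vectorised).
# Collinear touching is not flagged; sufficient for traced contours.
is_simple_polygon <- function(v) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[nxt, 1]; y2 <- v[nxt, 2]
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  adj <- (j == i + 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  d1 <- cross(x1[j] - x1[i], y1[j] - y1[i], x2[i] - x1[i], y2[i] - y1[i])
  d2 <- cross(x2[j] - x1[i], y2[j] - y1[i], x2[i] - x1[i], y2[i] - y1[i])
  d3 <- cross(x1[i] - x1[j], y1[i] - y1[j], x2[j] - x1[j], y2[j] - y1[j])
  d4 <- cross(x2[i] - x1[j], y2[i] - y1[j], x2[j] - x1[j], y2[j] - y1[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

pipeline_log <- function(level, stage, msg, log_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[log_level]]) {
    message(sprintf("[%s] stage=%s %s", level, stage, msg))
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesise (optional) -> score -> volumetry -> statistics ->
#' report, writing every intermediate and report file into `out_dir` so each
#' reported statistic is recomputable from the emitted files. With no input
#' paths a synthetic cohort is generated from `config`; alternatively
#' `inputs` may point at existing score/demographics/contour files, and a
#' scores-only run produces the vascular tables while marking the cardiac
#' tables absent.
#'
#' Outputs: `demographics.csv`, `segment_scores.csv`, `contours.json`
#' (synthetic runs); `sas_per_participant.csv`, `segment_counts.csv`,
#' `lv_metrics.csv` (when contours are present), `table1_demographics.csv`/
#' `.md`, `table2_mri_metrics.csv`/`.md`, `sas_boxplot_data.csv`,
#' `ancova.csv`, `agreement.csv` and `manifest.json`.
#'
#' All randomness (simulation, rescoring sample) is derived from `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()], or `NULL` for defaults.
#' @param config_path Optional YAML file with keys `seed`, `inputs`
#'   (`scores`/`demographics`/`contours` paths) and `cohort` (overrides
#'   passed to [cohort_config()]).
#' @param inputs Optional named list of input paths (same keys), overriding
#'   `config_path`.
#' @param seed Master seed (default 1).
#' @param rescore_n Number of participants rescored for the agreement
#'   analysis (default 20).
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return A run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(out_dir, config = NULL, config_path = NULL,
                         inputs = NULL, seed = 1L, rescore_n = 20L,
                         log_level = "info") {
  t0 <- Sys.time()
  if (!is.null(config_path)) {
    cf <- yaml::read_yaml(config_path)
    if (!is.null(cf$seed)) seed <- as.integer(cf$seed)
    if (is.null(inputs)) inputs <- cf$inputs
    if (is.null(config) && !is.null(cf$cohort)) {
      config <- do.call(cohort_config, cf$cohort)
    }
  }
  if (is.null(config)) config <- cohort_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- stage: simulate or load ---
  if (is.null(inputs) || is.null(inputs$scores)) {
    if (!is.null(inputs)) {
      stop("stage simulate/load failed: inputs given without 'scores'")
    }
    pipeline_log("info", "simulate", paste0("seed=", seed),
                 log_level = log_level)
    cohort <- generate_cohort(config, seed = seed, contours = TRUE)
    scores <- cohort$scores
    demographics <- cohort$demographics
    stacks <- cohort$stacks
    paths$demographics <- file.path(out_dir, "demographics.csv")
    paths$scores <- file.path(out_dir, "segment_scores.csv")
    paths$contours <- file.path(out_dir, "contours.json")
    write_demographics(demographics, paths$demographics)
    write_segment_scores(scores, paths$scores)
    write_contour_stacks(stacks, paths$contours)
  } else {
    pipeline_log("info", "load", paste(unlist(inputs), collapse = " "),
                 log_level = log_level)
    scores <- read_segment_scores(inputs$scores)
    if (is.null(inputs$demographics)) {
      stop("stage load failed: missing demographics input")
    }
    demographics <- read_demographics(inputs$demographics)
    stacks <- if (!is.null(inputs$contours)) {
      read_contour_stacks(inputs$contours)
    } else NULL
    paths[names(inputs)] <- unlist(inputs)
  }

  issues <- validate_inputs(scores = scores, demographics = demographics,
                            stacks = stacks)
  if (nrow(issues)) {
    utils::write.csv(issues, file.path(out_dir, "validation_issues.csv"),
                     row.names = FALSE)
    pipeline_log("warn", "validate", paste0(nrow(issues), " issues"),
                 log_level = log_level)
  }

  # --- stage: score ---
  r1 <- scores[scores$read_id == unique(scores$read_id)[1], , drop = FALSE]
  sas <- score_cohort(r1)
  sas$group <- demographics$group[match(sas$participant_id,
                                        demographics$participant_id)]
  paths$sas <- file.path(out_dir, "sas_per_participant.csv")
  utils::write.csv(sas, paths$sas, row.names = FALSE, na = "")
  counts <- summarize_segment_counts(r1, group = demographics)
  paths$counts <- file.path(out_dir, "segment_counts.csv")
  utils::write.csv(counts, paths$counts, row.names = FALSE)
  pipeline_log("info", "score",
               paste0("participants=", nrow(sas)), log_level = log_level)

  # --- stage: volumetry ---
  lv <- NULL
  if (!is.null(stacks)) {
    rows <- lapply(names(stacks), function(pid) {
      st <- stacks[[pid]]
      drow <- demographics[demographics$participant_id == pid, , drop = FALSE]
      if (!nrow(drow)) stop("stage volumetry failed: no demographics for ",
                            pid)
      m <- derive_metrics(st$ED, st$ES, drow$height_cm, drow$weight_kg)
      data.frame(participant_id = pid, group = drow$group,
                 lvedv = m$lvedv, lvesv = m$lvesv, lvsv = m$lvsv,
                 lvef = m$lvef, lvm = m$lvm, lvmvr = m$lvmvr,
                 lvgfi = m$lvgfi, bsa = m$bsa, lvedv_i = m$lvedv_i,
                 lvesv_i = m$lvesv_i, lvsv_i = m$lvsv_i, lvm_i = m$lvm_i,
                 stringsAsFactors = FALSE)
    })
    lv <- do.call(rbind, rows)
    paths$lv <- file.path(out_dir, "lv_metrics.csv")
    utils::write.csv(lv, paths$lv, row.names = FALSE)
    pipeline_log("info", "volumetry", paste0("participants=", nrow(lv)),
                 log_level = log_level)
  } else {
    pipeline_log("info", "volumetry", "skipped: no contours",
                 log_level = log_level)
  }

  # --- stage: stats + report ---
  t1 <- build_table1(demographics)
  utils::write.csv(t1, file.path(out_dir, "table1_demographics.csv"),
                   row.names = FALSE)
  writeLines(markdown_table(t1),
             file.path(out_dir, "table1_demographics.md"))
  t2 <- build_table2(sas, counts, lv, demographics)
  utils::write.csv(t2, file.path(out_dir, "table2_mri_metrics.csv"),
                   row.names = FALSE)
  writeLines(markdown_table(t2),
             file.path(out_dir, "table2_mri_metrics.md"))

  box <- sas[!is.na(sas$wb_sas), c("participant_id", "group", "wb_sas")]
  utils::write.csv(box, file.path(out_dir, "sas_boxplot_data.csv"),
                   row.names = FALSE)

  anc <- ancova_report(sas, lv, demographics)
  utils::write.csv(anc, file.path(out_dir, "ancova.csv"), row.names = FALSE)

  agree <- agreement_report(scores, config, seed, rescore_n)
  utils::write.csv(agree, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)
  pipeline_log("info", "report", "tables written", log_level = log_level)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wbcvmr")),
    seed = seed,
    config_hash = config_hash(config),
    cardiac = if (is.null(lv)) "absent" else "present",
    n_participants = nrow(demographics),
    n_segment_rows = nrow(scores),
    paths = paths,
    outputs = union(list.files(out_dir), "manifest.json"),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

fmt_p <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "<0.001" else sprintf("%.3g", p)
}

comparison_row <- function(variable, values, group) {
  cmp <- tryCatch(
    suppressWarnings(compare_groups(values, group, variable = variable)),
    error = function(e) NULL)
  if (is.null(cmp)) {
    return(data.frame(variable = variable, group1 = "", group2 = "",
                      group3 = "", group4 = "", p = "", test = "",
                      stringsAsFactors = FALSE))
  }
  mk <- significance_markers(cmp)
  cell <- function(g) {
    if (!g %in% cmp$groups) return("")
    paste0(cmp$summaries[[g]]$label, mk[[g]])
  }
  data.frame(variable = variable, group1 = cell("1"), group2 = cell("2"),
             group3 = cell("3"), group4 = cell("4"),
             p = fmt_p(cmp$omnibus_p), test = cmp$test,
             stringsAsFactors = FALSE)
}

proportion_row <- function(variable, flag, group) {
  tab <- table(factor(group, levels = 1:4), factor(flag, levels = 0:1))
  p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                error = function(e) NA_real_)
  cell <- function(g) {
    n <- tab[g, "1"]; tot <- sum(tab[g, ])
    if (tot == 0) "" else sprintf("%d (%.0f %%)", n, 100 * n / tot)
  }
  data.frame(variable = variable, group1 = cell("1"), group2 = cell("2"),
             group3 = cell("3"), group4 = cell("4"), p = fmt_p(p),
             test = "chi_square", stringsAsFactors = FALSE)
}

build_table1 <- function(demographics) {
  d <- demographics
  rows <- list(
    data.frame(variable = "N",
               group1 = as.character(sum(d$group == 1)),
               group2 = as.character(sum(d$group == 2)),
               group3 = as.character(sum(d$group == 3)),
               group4 = as.character(sum(d$group == 4)), p = "", test = "",
               stringsAsFactors = FALSE),
    proportion_row("male (%)", d$sex, d$group),
    comparison_row("age (years)", d$age, d$group),
    comparison_row("BMI (kg/m2)", d$bmi, d$group),
    proportion_row("hypertension", d$hypertension, d$group),
    proportion_row("current/ex smoker", d$smoker, d$group),
    comparison_row("HbA1c", d$hba1c, d$group)
  )
  do.call(rbind, rows)
}

build_table2 <- function(sas, counts, lv, demographics) {
  rows <- list(comparison_row("WB SAS", sas$wb_sas, sas$group))
  terr_labels <- c(head_neck = "head/neck SAS", aorta = "aorta SAS",
                   abdominal = "abdomen SAS",
                   iliofemoral = "ilio-femoral SAS", runoff = "run-off SAS")
  for (tt in names(terr_labels)) {
    rows[[length(rows) + 1L]] <-
      comparison_row(terr_labels[[tt]], sas[[paste0("sas_", tt)]],
                     sas$group)
  }
  cnt_row <- function(variable, col) {
    cc <- counts[counts$group != "overall", , drop = FALSE]
    cell <- function(g) {
      r <- cc[cc$group == g, , drop = FALSE]
      if (!nrow(r)) "" else as.character(round(r[[col]], 1))
    }
    data.frame(variable = variable, group1 = cell("1"), group2 = cell("2"),
               group3 = cell("3"), group4 = cell("4"), p = "",
               test = "count", stringsAsFactors = FALSE)
  }
  rows <- c(rows, list(
    cnt_row("normal vessels", "grade0"),
    cnt_row("vessels with 1-50 % stenosis", "grade1"),
    cnt_row("vessels with 51-70 % stenosis", "grade2"),
    cnt_row("vessels with 71-99 % stenosis", "grade3"),
    cnt_row("occluded vessels", "grade4"),
    cnt_row("abnormal vessels per participant", "abnormal_per_participant"),
    cnt_row("N with >50 % stenosis in any vessel", "n_gt50_any_vessel")
  ))
  if (!is.null(lv)) {
    rows <- c(rows, list(
      comparison_row("LVM (g/m2)", lv$lvm_i, lv$group),
      comparison_row("LVEDV (ml/m2)", lv$lvedv_i, lv$group),
      comparison_row("LVESV (ml/m2)", lv$lvesv_i, lv$group),
      comparison_row("LVEF (%)", lv$lvef, lv$group),
      comparison_row("LVSV (ml/m2)", lv$lvsv_i, lv$group),
      comparison_row("LVMVR (g/ml)", lv$lvmvr, lv$group),
      comparison_row("LVGFI", lv$lvgfi, lv$group)
    ))
  } else {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "cardiac MRI metrics", group1 = "absent",
      group2 = "absent", group3 = "absent", group4 = "absent",
      p = "", test = "no contour input", stringsAsFactors = FALSE)
  }
  if (!is.null(demographics$lge)) {
    rows[[length(rows) + 1L]] <-
      proportion_row("LGE (%)", demographics$lge, demographics$group)
  }
  do.call(rbind, rows)
}

ancova_report <- function(sas, lv, demographics) {
  d <- demographics
  base <- d[c("participant_id", "group", "age", "sex", "bmi",
              "hypertension", "smoker")]
  out <- list()
  run_one <- function(dep_name, values, ids) {
    df <- base
    df[[dep_name]] <- values[match(df$participant_id, ids)]
    a <- tryCatch(ancova_adjust(df, dep_name), error = function(e) NULL)
    if (is.null(a)) return(NULL)
    cbind(data.frame(dependent = dep_name, group_p = a$group_p,
                     stringsAsFactors = FALSE),
          a$contrasts[, c("contrast", "estimate", "p_bonferroni")])
  }
  out$sas <- run_one("wb_sas", sas$wb_sas, sas$participant_id)
  if (!is.null(lv)) {
    out$lvm <- run_one("lvm_i", lv$lvm_i, lv$participant_id)
  }
  do.call(rbind, out)
}

agreement_report <- function(scores, config, seed, rescore_n) {
  r1 <- scores[scores$read_id == unique(scores$read_id)[1], , drop = FALSE]
  pids <- unique(r1$participant_id)
  rescore_n <- min(rescore_n, length(pids))
  set.seed(seed + 7L)
  sel <- sample(pids, rescore_n)
  sub <- r1[r1$participant_id %in% sel, , drop = FALSE]
  r2 <- rescore_with_noise(sub, config$noise$rescore_shift_p,
                           seed = seed + 8L)
  sas1 <- wb_sas_fast(sub)
  sas2 <- wb_sas_fast(r2)
  keep <- !is.na(sas1) & !is.na(sas2)
  res <- icc_2_1(cbind(sas1[keep], sas2[keep]))
  data.frame(metric = "WB SAS", model = res$model, n = res$n,
             icc = res$icc, ci_lower = res$lower, ci_upper = res$upper,
             p_value = res$p_value, stringsAsFactors = FALSE)
}

markdown_table <- function(df) {
  esc <- function(x) gsub("\\|", "/", as.character(x))
  header <- paste0("| ", paste(esc(names(df)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(esc(unlist(df[i, ])), collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}
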
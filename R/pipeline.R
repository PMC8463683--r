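# End-to-end orchestration: simulate -> calibrate -> estimate metacognition
# -> fit the checking and accuracy mixed models -> report. All stages are
# seeded; a JSON-lines log records one entry per stage.

#' Build a run configuration
#'
#' @param cohort A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param calibrate Run the adaptive calibration + outlier exclusion stage.
#' @param fit_models Fit the checking-count and accuracy mixed models.
#' @param n_boot Bootstrap replicates for coefficient CIs (0 = skip).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = tempfile("metacheck_run_"),
                       seed = 1L, calibrate = TRUE, fit_models = TRUE,
                       n_boot = 0L) {
  structure(list(cohort = cohort, out_dir = out_dir, seed = as.integer(seed),
                 calibrate = calibrate, fit_models = fit_models,
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

log_stage <- function(path, stage, seed, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, seed = seed), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a mechanistic observer cohort; (2) adaptive
#' calibration of each subject's psychometric curve and application of the
#' group outlier-exclusion rule; (3) per-subject metacognition estimates
#' (M-ratio from the explicit task, CMI from the implicit task); (4) fits of
#' the Poisson checking model and logistic accuracy model using the
#' estimated trait measures as covariates; (5) group tests (signed-rank
#' tests of M-ratio and CMI against zero, trait correlations) and tercile
#' descriptives. Writes CSV artifacts plus a JSON-lines run log; the run is
#' deterministic given the seeds.
#'
#' @param config A [run_config()].
#' @return A `report_table` list with `subjects`, `m1`, `m2`, `tests`,
#'   `terciles`, `exclusions` and `paths` of artifacts on disk.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  stage_seed <- function(i) child_seed(config$seed, i)
  fail <- function(stage, e) stop(sprintf("pipeline stage `%s` failed: %s",
                                          stage, conditionMessage(e)), call. = FALSE)

  # 1. simulate
  cohort <- tryCatch(simulate_cohort(config$cohort, seed = stage_seed(1)),
                     error = function(e) fail("simulate", e))
  log_stage(log_path, "simulate", stage_seed(1),
            n_subjects = config$cohort$n_subjects, n_trials = nrow(cohort$trials))

  # 2. calibrate + exclusions
  kept <- cohort$subjects$subject_id
  exclusions <- NULL
  calib <- NULL
  if (config$calibrate) {
    calib <- tryCatch({
      fits <- lapply(cohort$profiles, function(pr)
        adaptive_calibration(pr, n_trials = config$cohort$n_calibration,
                             seed = child_seed(config$seed, 100 + pr$subject_id))$fit)
      data.frame(subject_id = cohort$subjects$subject_id,
                 slope = vapply(fits, `[[`, numeric(1), "slope"),
                 inflexion = vapply(fits, `[[`, numeric(1), "inflexion"))
    }, error = function(e) fail("calibrate", e))
    excl <- tryCatch(reject_outlier_subjects(calib),
                     error = function(e) fail("exclude", e))
    kept <- excl$kept
    exclusions <- excl$report
    log_stage(log_path, "calibrate", stage_seed(2),
              n_kept = length(kept), n_discarded = length(excl$discarded))
  }

  # 3. metacognition estimates
  measures <- tryCatch({
    do.call(rbind, lapply(kept, function(s) {
      tr <- cohort$trials
      expl <- tr[tr$task == "explicit" & tr$subject_id == s, ]
      imp <- tr[tr$task == "implicit" & tr$subject_id == s, ]
      md <- fit_meta_d(build_rating_table(expl))
      ci <- compute_cmi(imp)
      data.frame(subject_id = s,
                 d_prime = md$d_prime,
                 m_ratio = if (md$defined) md$m_ratio else NA_real_,
                 cmi = if (ci$defined) ci$cmi else NA_real_)
    }))
  }, error = function(e) fail("metacog", e))
  subjects <- merge(measures,
                    cohort$subjects[, c("subject_id", "padua_score",
                                        "mistrust_score")],
                    by = "subject_id")
  log_stage(log_path, "metacog", stage_seed(3),
            n_subjects = nrow(subjects),
            n_mratio_defined = sum(!is.na(subjects$m_ratio)))

  # 4. mixed models on the checking task, using estimated trait measures
  m1 <- m2 <- NULL
  chk <- cohort$trials[cohort$trials$task == "checking" &
                         cohort$trials$subject_id %in% kept, ]
  if (config$fit_models) {
    mtab <- subjects
    mtab$mratio <- mtab$m_ratio; mtab$cmi_est <- mtab$cmi
    idx <- match(chk$subject_id, mtab$subject_id)
    chk$mratio <- mtab$mratio[idx]
    chk$cmi <- mtab$cmi_est[idx]
    chk$padua <- mtab$padua_score[idx]
    chk$mistrust <- mtab$mistrust_score[idx]
    chk$checks <- chk$n_checks
    ok <- stats::complete.cases(chk[, c("n_checks", "difficulty", "mratio",
                                        "cmi", "padua", "mistrust", "correct")])
    chk_fit <- chk[ok, ]
    m1 <- tryCatch(fit_glmm(m1_spec(), chk_fit),
                   error = function(e) fail("fit-m1", e))
    log_stage(log_path, "fit-m1", config$seed, logLik = m1$logLik,
              converged = m1$converged)
    m2 <- tryCatch(fit_glmm(m2_spec(), chk_fit),
                   error = function(e) fail("fit-m2", e))
    log_stage(log_path, "fit-m2", config$seed, logLik = m2$logLik,
              converged = m2$converged)
  }

  # 5. group tests + descriptives
  tests <- tryCatch({
    mr <- subjects$m_ratio[!is.na(subjects$m_ratio) & subjects$m_ratio != 0]
    cm <- subjects$cmi[!is.na(subjects$cmi) & subjects$cmi != 0]
    rbind(
      test_row("mratio_gt0", wilcoxon_signed_rank(mr, method = "normal_cc")),
      test_row("cmi_gt0", wilcoxon_signed_rank(cm, method = "normal_cc")),
      test_row("mratio_cmi_corr",
               correlate_measures(subjects, list(c("m_ratio", "cmi")))[[1]]),
      test_row("padua_mistrust_corr",
               correlate_measures(subjects,
                                  list(c("padua_score", "mistrust_score")))[[1]])
    )
  }, error = function(e) fail("tests", e))
  terciles <- tryCatch(tercile_descriptives(chk),
                       error = function(e) fail("terciles", e))
  log_stage(log_path, "report", config$seed)

  # artifacts
  paths <- c(
    cohort = file.path(config$out_dir, "cohort.csv"),
    subjects = file.path(config$out_dir, "subjects.csv"),
    tests = file.path(config$out_dir, "tests.csv")
  )
  write_cohort(cohort$trials, config$cohort, paths[["cohort"]])
  utils::write.csv(subjects, paths[["subjects"]], row.names = FALSE)
  utils::write.csv(tests, paths[["tests"]], row.names = FALSE)
  if (!is.null(m1)) {
    paths[["m1"]] <- file.path(config$out_dir, "m1_coefficients.csv")
    paths[["m2"]] <- file.path(config$out_dir, "m2_coefficients.csv")
    utils::write.csv(coef_table_with_ci(m1, config), paths[["m1"]],
                     row.names = FALSE)
    utils::write.csv(coef_table_with_ci(m2, config), paths[["m2"]],
                     row.names = FALSE)
  }
  structure(list(subjects = subjects, m1 = m1, m2 = m2, tests = tests,
                 terciles = terciles, exclusions = exclusions,
                 calibration = calib, cohort = cohort, paths = paths,
                 log = log_path),
            class = "report_table")
}

test_row <- function(name, tr) {
  data.frame(test = name, statistic = unname(tr$statistic[1]),
             stat_name = names(tr$statistic)[1],
             n = tr$n %||% NA, p_value = tr$p_value, method = tr$method)
}

coef_table_with_ci <- function(fit, config) {
  tab <- wald_table(fit)
  if (config$n_boot > 0 && fit$converged) {
    ci <- parametric_bootstrap_ci(fit, n_boot = config$n_boot,
                                  seed = child_seed(config$seed, 999))
    tab$ci_low <- ci$ci_low; tab$ci_high <- ci$ci_high
  }
  tab
}

#' Within-subject tercile descriptives
#'
#' Bins each subject's trials into difficulty terciles (by coherence, hardest
#' = lowest coherence), then averages within-subject means across subjects.
#' Reports mean checks per tercile and accuracy per tercile crossed with a
#' checks bin (`0`, `1`, `2+`). Subjects with fewer than 3 distinct
#' coherences are skipped with a warning.
#'
#' @param trials Checking-task trial records (`subject_id`, `coherence`,
#'   `n_checks`, `correct`).
#' @return List of data frames `checks` (tercile, mean, sem, n_subjects) and
#'   `accuracy` (tercile, checks_bin, mean, sem, n_subjects).
#' @export
tercile_descriptives <- function(trials) {
  check_columns(trials, c("subject_id", "coherence", "n_checks", "correct"),
                "checking trials")
  per_subj <- split(trials, trials$subject_id)
  chk_rows <- list(); acc_rows <- list()
  for (s in names(per_subj)) {
    tr <- per_subj[[s]]
    if (length(unique(tr$coherence)) < 3L) {
      warning(sprintf("subject %s has < 3 distinct coherences; skipped", s),
              call. = FALSE)
      next
    }
    qs <- stats::quantile(tr$coherence, c(1 / 3, 2 / 3), type = 7)
    # tercile 1 = easiest (highest coherence), 3 = hardest
    terc <- 3L - findInterval(tr$coherence, qs, left.open = TRUE)
    bin <- cut(tr$n_checks, c(-Inf, 0, 1, Inf), labels = c("0", "1", "2+"))
    chk_rows[[s]] <- data.frame(subject = s, tercile = 1:3,
                                checks = tapply(tr$n_checks, factor(terc, 1:3),
                                                mean))
    acc <- expand.grid(tercile = 1:3, checks_bin = levels(bin))
    acc$accuracy <- mapply(function(tc, b) {
      sel <- terc == tc & bin == b
      if (any(sel)) mean(tr$correct[sel]) else NA_real_
    }, acc$tercile, acc$checks_bin)
    acc$subject <- s
    acc_rows[[s]] <- acc
  }
  if (!length(chk_rows)) abort_input("no subject had >= 3 distinct coherences")
  chk <- do.call(rbind, chk_rows)
  acc <- do.call(rbind, acc_rows)
  sem <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  checks_out <- do.call(rbind, lapply(split(chk, chk$tercile), function(d)
    data.frame(tercile = d$tercile[1], mean = mean(d$checks, na.rm = TRUE),
               sem = sem(d$checks), n_subjects = sum(!is.na(d$checks)))))
  acc_out <- do.call(rbind, lapply(split(acc, list(acc$tercile, acc$checks_bin)),
                                   function(d)
    data.frame(tercile = d$tercile[1], checks_bin = d$checks_bin[1],
               mean = mean(d$accuracy, na.rm = TRUE), sem = sem(d$accuracy),
               n_subjects = sum(!is.na(d$accuracy)))))
  rownames(checks_out) <- rownames(acc_out) <- NULL
  list(checks = checks_out, accuracy = acc_out)
}

#' Correlate per-subject measures
#'
#' Pearson correlation tests between pairs of subject-level columns.
#'
#' @param subjects Per-subject data frame.
#' @param pairs List of length-2 character vectors naming column pairs.
#' @return Named list of `test_result`s.
#' @export
correlate_measures <- function(subjects, pairs) {
  out <- list()
  for (pr in pairs) {
    check_columns(subjects, pr, "subject table")
    ok <- stats::complete.cases(subjects[, pr])
    if (sum(ok) < 3) abort_input("fewer than 3 complete subjects for %s ~ %s",
                                 pr[1], pr[2])
    out[[paste(pr, collapse = "~")]] <-
      pearson_correlation_test(subjects[[pr[1]]][ok], subjects[[pr[2]]][ok])
  }
  out
}
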
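# Synthetic-cohort generators: a mechanistic signal-detection observer mode
# (for the metacognition estimators) and a GLMM mode whose generative truth is
# exactly the checking-count and accuracy mixed models (for coefficient
# recovery).

TASKS <- c("calibration", "checking", "implicit", "explicit")

#' Simulate 2AFC observer trials
#'
#' Equal-variance Gaussian observer: on each trial sensory evidence is drawn
#' from `N(direction * sensitivity_k * coherence, 1)` and the response is the
#' sign of the evidence, so accuracy at coherence `c` is `pnorm(k * c)`. For
#' the explicit task a confidence evidence variable `|evidence| + N(0,
#' meta_noise_sigma)` is mapped through the subject's five cutpoints to a
#' rating 1-6.
#'
#' @param profile A [subject_profile()].
#' @param coherence Vector of coherences in `[0, 1]`.
#' @param task One of `"calibration"`, `"checking"`, `"implicit"`,
#'   `"explicit"`.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A data frame of trial records with columns `subject_id`, `task`,
#'   `coherence`, `direction`, `response`, `correct`, and `confidence` for the
#'   explicit task.
#' @export
simulate_observer_trials <- function(profile, coherence, task = "calibration",
                                     seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.character(task) || length(task) != 1L || !task %in% TASKS)
    abort_input("unknown task kind: %s", paste(task, collapse = ","))
  if (any(!is.finite(coherence)) || any(coherence < 0) || any(coherence > 1))
    abort_input("coherence must lie in [0, 1]")
  with_seed(seed, {
    n <- length(coherence)
    direction <- sample(c(-1L, 1L), n, replace = TRUE)
    evidence <- stats::rnorm(n, mean = direction * profile$sensitivity_k * coherence)
    response <- ifelse(evidence >= 0, 1L, -1L)
    out <- data.frame(
      subject_id = profile$subject_id,
      task = task,
      coherence = coherence,
      direction = direction,
      response = response,
      correct = as.integer(response == direction),
      stringsAsFactors = FALSE
    )
    out$evidence <- evidence
    if (task == "explicit") {
      conf_ev <- abs(evidence) + stats::rnorm(n, 0, profile$meta_noise_sigma)
      out$confidence <- rating_from_evidence(conf_ev, profile$confidence_thresholds)
    }
    out
  })
}

#' Single-trial wrapper around [simulate_observer_trials()]
#' @inheritParams simulate_observer_trials
#' @return A one-row trial record.
#' @export
simulate_observer_trial <- function(profile, coherence, task = "calibration",
                                    seed = NULL) {
  check_number(coherence, "coherence", min = 0, max = 1)
  simulate_observer_trials(profile, coherence, task, seed)
}

# Map confidence evidence to a 1..6 rating through ascending cutpoints.
rating_from_evidence <- function(conf_ev, thresholds) {
  findInterval(conf_ev, thresholds) + 1L
}

#' Simulate confidence forced-choice pairs
#'
#' Each pair presents two stimuli; after both orientation judgments the
#' observer picks the trial with the larger confidence evidence
#' (`|evidence| + meta-noise`), optionally corrupted by logistic choice noise.
#' Exactly one member of each pair is chosen.
#'
#' @param profile A [subject_profile()].
#' @param coherence_a,coherence_b Coherences of the two stimuli per pair
#'   (vectors of equal length, values in `[0, 1]`).
#' @param choice_noise Logistic temperature; 0 gives a deterministic argmax
#'   chooser, `Inf` a uniformly random chooser.
#' @param seed Optional seed.
#' @return Trial records (two rows per pair) with `pair_id` and logical
#'   `chosen`.
#' @export
simulate_implicit_pairs <- function(profile, coherence_a, coherence_b,
                                    choice_noise = 0, seed = NULL) {
  if (length(coherence_a) != length(coherence_b))
    abort_input("coherence_a and coherence_b must have equal length")
  if (any(c(coherence_a, coherence_b) < 0) || any(c(coherence_a, coherence_b) > 1))
    abort_input("coherence must lie in [0, 1]")
  with_seed(seed, {
    n <- length(coherence_a)
    a <- simulate_observer_trials(profile, coherence_a, task = "implicit")
    b <- simulate_observer_trials(profile, coherence_b, task = "implicit")
    conf <- function(tr) abs(tr$evidence) +
      stats::rnorm(nrow(tr), 0, profile$meta_noise_sigma)
    ca <- conf(a); cb <- conf(b)
    p_a <- if (is.infinite(choice_noise)) rep(0.5, n)
           else if (choice_noise == 0) as.numeric(ca > cb) + 0.5 * (ca == cb)
           else stats::plogis((ca - cb) / choice_noise)
    pick_a <- stats::runif(n) < p_a
    a$pair_id <- seq_len(n); b$pair_id <- seq_len(n)
    a$chosen <- pick_a; b$chosen <- !pick_a
    out <- rbind(a, b)
    out[order(out$pair_id), , drop = FALSE]
  })
}

#' Simulate checking counts from the log-linear Poisson policy
#'
#' Draws per-trial numbers of checks from
#' `Poisson(exp(b0 + b_diff * z + sum(b_k t_k) + sum(g_k t_k z) + u + e))`
#' with a subject random intercept `u ~ N(0, subject_sd^2)` and an
#' observation-level (per-trial) intercept `e ~ N(0, olre_sd^2)` absorbing
#' overdispersion.
#'
#' @param design Data frame with columns `subject_id`, `difficulty`
#'   (standardized; higher = harder), and trait covariates `mratio`, `cmi`,
#'   `padua`, `mistrust` (standardized).
#' @param coefficients Coefficient list, see [m1_coefficients()].
#' @param subject_intercepts Optional named numeric vector of subject offsets;
#'   drawn from `N(0, subject_sd^2)` when omitted.
#' @param seed Optional seed.
#' @return `design` with an added integer column `n_checks`.
#' @export
simulate_checking_counts <- function(design, coefficients = m1_coefficients(),
                                     subject_intercepts = NULL, seed = NULL) {
  check_columns(design, c("subject_id", "difficulty", "mratio", "cmi",
                          "padua", "mistrust"), "checking design")
  cf <- coefficients
  with_seed(seed, {
    subjects <- unique(design$subject_id)
    if (is.null(subject_intercepts)) {
      subject_intercepts <- stats::rnorm(length(subjects), 0, cf$subject_sd)
      names(subject_intercepts) <- as.character(subjects)
    }
    u <- subject_intercepts[as.character(design$subject_id)]
    e <- stats::rnorm(nrow(design), 0, cf$olre_sd)
    z <- design$difficulty
    eta <- cf$intercept + cf$difficulty * z +
      cf$mratio * design$mratio + cf$cmi * design$cmi +
      cf$padua * design$padua + cf$mistrust * design$mistrust +
      cf$mratio_difficulty * design$mratio * z +
      cf$cmi_difficulty * design$cmi * z +
      cf$padua_difficulty * design$padua * z +
      cf$mistrust_difficulty * design$mistrust * z +
      u + e
    if (any(!is.finite(eta))) {
      bad <- names(cf)[!vapply(cf, is.finite, logical(1))]
      abort_input("non-finite linear predictor in checking model%s",
                  if (length(bad)) paste0(" (offending coefficients: ",
                                          paste(bad, collapse = ", "), ")") else "")
    }
    design$n_checks <- stats::rpois(nrow(design), exp(eta))
    design
  })
}

#' Simulate trial accuracy from the logistic model
#'
#' Adds Bernoulli accuracy outcomes using the accuracy model's linear
#' predictor: difficulty, standardized checks, checks-by-difficulty, trait
#' main effects and trait-by-checks interactions, plus a subject random
#' intercept.
#'
#' @param design Data frame with `subject_id`, `difficulty`, `n_checks` and
#'   trait columns; `checks_z` (standardized checks) is computed from
#'   `n_checks` when absent.
#' @param coefficients Coefficient list, see [m2_coefficients()].
#' @param subject_intercepts Optional named subject offsets.
#' @param seed Optional seed.
#' @return `design` with added columns `checks_z` and `correct`.
#' @export
simulate_accuracy <- function(design, coefficients = m2_coefficients(),
                              subject_intercepts = NULL, seed = NULL) {
  check_columns(design, c("subject_id", "difficulty", "mratio", "cmi",
                          "padua", "mistrust"), "accuracy design")
  if (!"n_checks" %in% names(design))
    abort_input("accuracy design is missing `n_checks`; generate counts first")
  cf <- coefficients
  with_seed(seed, {
    if (!"checks_z" %in% names(design)) {
      s <- stats::sd(design$n_checks)
      design$checks_z <- if (s > 0) (design$n_checks - mean(design$n_checks)) / s
                         else design$n_checks * 0
    }
    subjects <- unique(design$subject_id)
    if (is.null(subject_intercepts)) {
      subject_intercepts <- stats::rnorm(length(subjects), 0, cf$subject_sd)
      names(subject_intercepts) <- as.character(subjects)
    }
    u <- subject_intercepts[as.character(design$subject_id)]
    z <- design$difficulty; ck <- design$checks_z
    eta <- cf$intercept + cf$difficulty * z + cf$checks * ck +
      cf$checks_difficulty * ck * z +
      cf$mratio * design$mratio + cf$cmi * design$cmi +
      cf$padua * design$padua + cf$mistrust * design$mistrust +
      cf$mratio_checks * design$mratio * ck +
      cf$cmi_checks * design$cmi * ck +
      cf$padua_checks * design$padua * ck +
      cf$mistrust_checks * design$mistrust * ck +
      u
    design$correct <- as.integer(stats::runif(nrow(design)) < stats::plogis(eta))
    design
  })
}

#' Draw questionnaire scores
#'
#' Gaussian draws at the configured mean/SD, clipped to the instrument range
#' and rounded to integer scores.
#'
#' @param n Number of subjects.
#' @param instrument Config list with `mean`, `sd`, `min`, `max` (see
#'   [questionnaire_defaults()]).
#' @param seed Optional seed.
#' @return Integer vector of length `n`.
#' @export
sample_questionnaires <- function(n, instrument, seed = NULL) {
  if (instrument$sd < 0) abort_input("questionnaire sd must be >= 0")
  with_seed(seed, {
    x <- stats::rnorm(n, instrument$mean, instrument$sd)
    as.integer(round(pmin(pmax(x, instrument$min), instrument$max)))
  })
}

#' Generate a GLMM-mode cohort
#'
#' Generative truth is exactly the checking-count and accuracy mixed models:
#' trial difficulty and trait covariates are drawn standardized, check counts
#' come from the Poisson policy (subject intercept + observation-level
#' effect), and accuracy from the logistic model using the realized,
#' cohort-standardized check counts. Used for coefficient-recovery testing.
#'
#' @param config A [cohort_config()].
#' @param n_trials Trials per subject (default: checking-task count).
#' @param seed Optional override of `config$seed`.
#' @return Data frame with one row per trial: `subject_id`, `trial`,
#'   `difficulty`, trait covariates, `n_checks`, `checks_z`, `correct`, plus
#'   per-subject raw questionnaire scores.
#' @export
simulate_glmm_cohort <- function(config = cohort_config(), n_trials = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  n_trials <- n_trials %||% config$n_checking
  ns <- config$n_subjects
  with_seed(seed, {
    rho <- config$trait_correlation
    mr <- stats::rnorm(ns)
    cmi <- rho * mr + sqrt(1 - rho^2) * stats::rnorm(ns)
    traits <- data.frame(
      subject_id = seq_len(ns),
      mratio = mr, cmi = cmi,
      padua = stats::rnorm(ns), mistrust = stats::rnorm(ns)
    )
    traits$padua_score <- sample_questionnaires_from_z(traits$padua,
                                                       config$questionnaires$padua)
    traits$mistrust_score <- sample_questionnaires_from_z(traits$mistrust,
                                                          config$questionnaires$mistrust)
    idx <- rep(seq_len(ns), each = n_trials)
    design <- traits[idx, c("subject_id", "mratio", "cmi", "padua", "mistrust")]
    design$trial <- rep(seq_len(n_trials), times = ns)
    design$difficulty <- stats::rnorm(ns * n_trials)
    design <- simulate_checking_counts(design, config$m1)
    design <- simulate_accuracy(design, config$m2)
    rownames(design) <- NULL
    merge(design, traits[, c("subject_id", "padua_score", "mistrust_score")],
          by = "subject_id", sort = FALSE)
  })
}

# Deterministic raw score from a standardized trait draw (clip + round).
sample_questionnaires_from_z <- function(z, instrument) {
  as.integer(round(pmin(pmax(instrument$mean + instrument$sd * z,
                             instrument$min), instrument$max)))
}

#' Generate a mechanistic observer cohort
#'
#' Draws subject profiles (sensitivity, meta-noise, traits, questionnaires)
#' and simulates the three post-calibration tasks from the signal-detection
#' observer: checking trials with Poisson check counts, implicit confidence
#' forced-choice pairs, and explicit confidence-rating trials. Coherences are
#' placed so accuracy spans roughly 50-100% per subject (inverse of the
#' subject's true psychometric curve).
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with `profiles` (list of [subject_profile()]), `subjects`
#'   (per-subject table) and `trials` (trial records across tasks).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  ns <- config$n_subjects
  with_seed(seed, {
    sens <- pmax(stats::rnorm(ns, config$sensitivity_mean, config$sensitivity_sd), 0.5)
    meta <- pmax(stats::rnorm(ns, config$meta_noise_mean, config$meta_noise_sd), 0)
    rho <- config$trait_correlation
    mr <- stats::rnorm(ns)
    cmi_t <- rho * mr + sqrt(1 - rho^2) * stats::rnorm(ns)
    padua <- sample_questionnaires(ns, config$questionnaires$padua)
    mistrust <- sample_questionnaires(ns, config$questionnaires$mistrust)
    u_m1 <- stats::rnorm(ns, 0, config$m1$subject_sd)
    profiles <- lapply(seq_len(ns), function(i)
      subject_profile(subject_id = i,
                      sensitivity_k = sens[i],
                      meta_noise_sigma = meta[i],
                      confidence_thresholds = config$confidence_thresholds,
                      random_intercept_m1 = u_m1[i],
                      padua_score = padua[i], mistrust_score = mistrust[i],
                      trait_mratio = mr[i], trait_cmi = cmi_t[i]))

    trial_frames <- lapply(profiles, function(pr) {
      # accuracy targets 0.525..0.975 -> coherences via the observer's own
      # probit curve, acc = pnorm(k * c)
      acc_grid <- seq(0.525, 0.975, length.out = 10)
      cset <- pmin(stats::qnorm(acc_grid) / pr$sensitivity_k, 1)

      chk <- simulate_observer_trials(pr, sample(cset, config$n_checking, TRUE),
                                      task = "checking")
      chk$difficulty <- -as.numeric(scale(chk$coherence))
      chk$mratio <- pr$trait_mratio; chk$cmi <- pr$trait_cmi
      chk$padua <- 0; chk$mistrust <- 0 # standardized later across cohort
      imp <- simulate_implicit_pairs(pr,
                                     sample(cset, config$n_implicit_pairs, TRUE),
                                     sample(cset, config$n_implicit_pairs, TRUE),
                                     choice_noise = config$choice_noise)
      imp$pair_id <- paste(pr$subject_id, imp$pair_id, sep = "-")
      exp_t <- simulate_observer_trials(pr, sample(cset, config$n_explicit, TRUE),
                                        task = "explicit")
      list(chk = chk, imp = imp, exp = exp_t)
    })

    chk <- do.call(rbind, lapply(trial_frames, `[[`, "chk"))
    # cohort-level standardized questionnaire covariates
    chk$padua <- standardize_by_subject(chk$subject_id, padua)
    chk$mistrust <- standardize_by_subject(chk$subject_id, mistrust)
    chk <- simulate_checking_counts(chk, config$m1,
                                    subject_intercepts = stats::setNames(u_m1, seq_len(ns)))
    # checking-task accuracy is generated by the logistic accuracy model so
    # that checking causally affects performance as configured
    chk <- simulate_accuracy(chk, config$m2)
    trials <- merge_trial_frames(chk,
                                 do.call(rbind, lapply(trial_frames, `[[`, "imp")),
                                 do.call(rbind, lapply(trial_frames, `[[`, "exp")))
    subjects <- data.frame(
      subject_id = seq_len(ns), sensitivity_k = sens, meta_noise_sigma = meta,
      trait_mratio = mr, trait_cmi = cmi_t,
      padua_score = padua, mistrust_score = mistrust
    )
    list(profiles = profiles, subjects = subjects, trials = trials)
  })
}

standardize_by_subject <- function(subject_id, scores) {
  z <- as.numeric(scale(scores))
  if (any(!is.finite(z))) z <- rep(0, length(scores))
  z[match(subject_id, seq_along(scores))]
}

merge_trial_frames <- function(...) {
  frames <- list(...)
  cols <- Reduce(union, lapply(frames, names))
  frames <- lapply(frames, function(f) {
    for (cl in setdiff(cols, names(f))) f[[cl]] <- NA
    f[, cols, drop = FALSE]
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk
#'
#' Writes the trial table as CSV and a JSON sidecar echoing the full cohort
#' configuration, including the seed, for provenance.
#'
#' @param cohort Result of [simulate_cohort()] or a trial data frame.
#' @param config The [cohort_config()] used to generate it.
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, config, path) {
  trials <- if (is.data.frame(cohort)) cohort else cohort$trials
  utils::write.csv(trials, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(unclass(config), sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = path, json = sidecar))
}
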
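# Cohort configuration and subject profiles for the synthetic-cohort module.

#' Questionnaire instrument definitions
#'
#' Group-level moments match a healthy adult cohort: Padua Inventory total
#' (60 items, range 0-240) and the cognitive-mistrust subscale of the
#' Metacognitions Questionnaire (10 items scored 1-4, range 10-40).
#'
#' @return Named list of instrument configs (`mean`, `sd`, `min`, `max`).
#' @export
questionnaire_defaults <- function() {
  list(
    padua    = list(mean = 57.6, sd = 28.8, min = 0,  max = 240),
    mistrust = list(mean = 20.5, sd = 6.3,  min = 10, max = 40)
  )
}

#' Default generative coefficients for the checking-count model
#'
#' Log-linear Poisson policy for the number of checks per trial:
#' `log E[checks] = b0 + b_difficulty * z + trait main effects +
#' trait-by-difficulty interactions + subject intercept + trial-level
#' (observation-level) intercept`. Printed trait-by-difficulty interaction
#' coefficients are used as defaults; unreported terms (intercept, trait
#' main effects, variance components) default to values giving a realistic
#' checking rate of about 0.6 checks per trial at average difficulty.
#'
#' @return Named list of coefficients and random-effect SDs.
#' @export
m1_coefficients <- function() {
  list(
    intercept          = log(0.6) - (0.5^2 + 0.5^2) / 2, # marginal mean 0.6 at z = 0
    difficulty         = 0.90,
    mratio             = 0,
    cmi                = 0,
    padua              = 0,
    mistrust           = 0,
    mratio_difficulty   = 0.08,
    cmi_difficulty      = -0.05,
    padua_difficulty    = 0.10,
    mistrust_difficulty = -0.09,
    subject_sd         = 0.5,
    olre_sd            = 0.5
  )
}

#' Default generative coefficients for the accuracy model
#'
#' Logistic model of trial accuracy with standardized difficulty, number of
#' checks, their interaction, trait main effects and trait-by-checks
#' interactions, plus a subject random intercept. The checks main effect
#' (-0.26) and checks-by-difficulty interaction (0.20) are the reported
#' estimates; the intercept targets ~70% accuracy and the difficulty slope
#' mirrors the perceptual effect.
#'
#' @return Named list of coefficients and the subject random-intercept SD.
#' @export
m2_coefficients <- function() {
  list(
    intercept         = qlogis(0.70),
    difficulty        = -0.90,
    checks            = -0.26,
    checks_difficulty = 0.20,
    mratio            = 0,
    cmi               = 0,
    padua             = 0,
    mistrust          = 0,
    mratio_checks     = 0,
    cmi_checks        = 0,
    padua_checks      = 0,
    mistrust_checks   = 0,
    subject_sd        = 0.8
  )
}

#' Build a cohort configuration
#'
#' Collects everything the synthetic-cohort generators need: cohort size,
#' per-task trial counts (defaults follow the experimental protocol: 120
#' calibration trials, ~218 checking trials, ~123 implicit pairs, ~113
#' explicit trials), generative coefficient sets for the checking-count and
#' accuracy models, questionnaire moments, and observer parameters for the
#' mechanistic mode.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_calibration,n_checking,n_implicit_pairs,n_explicit Trials per task.
#' @param m1,m2 Coefficient lists, see [m1_coefficients()], [m2_coefficients()].
#' @param questionnaires Instrument list, see [questionnaire_defaults()].
#' @param sensitivity_mean,sensitivity_sd Across-subject distribution of the
#'   perceptual sensitivity `k` (evidence units per unit coherence).
#' @param meta_noise_mean,meta_noise_sd Across-subject distribution of the
#'   second-order readout noise SD.
#' @param confidence_thresholds Five ascending cutpoints mapping confidence
#'   evidence to ratings 1-6.
#' @param choice_noise Logistic temperature of the confidence forced choice
#'   (0 = deterministic argmax).
#' @param trait_correlation Correlation planted between the standardized
#'   M-ratio and CMI trait covariates (default 0: independent).
#' @param seed Master seed; fixed seed gives byte-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 28,
                          n_calibration = 120,
                          n_checking = 218,
                          n_implicit_pairs = 123,
                          n_explicit = 113,
                          m1 = m1_coefficients(),
                          m2 = m2_coefficients(),
                          questionnaires = questionnaire_defaults(),
                          sensitivity_mean = 5.2,
                          sensitivity_sd = 1.5,
                          meta_noise_mean = 0.5,
                          meta_noise_sd = 0.2,
                          confidence_thresholds = c(0.5, 1.0, 1.5, 2.0, 2.5),
                          choice_noise = 0,
                          trait_correlation = 0,
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", min = 2)
  for (nm in c("n_calibration", "n_checking", "n_implicit_pairs", "n_explicit"))
    check_number(get(nm), nm, min = 1)
  if (m1$subject_sd < 0 || m1$olre_sd < 0 || m2$subject_sd < 0)
    abort_input("random-effect SDs must be >= 0")
  for (q in names(questionnaires))
    if (questionnaires[[q]]$sd < 0)
      abort_input("questionnaire `%s` has negative sd", q)
  if (any(diff(confidence_thresholds) <= 0) || length(confidence_thresholds) != 5L)
    abort_input("confidence_thresholds must be 5 strictly increasing cutpoints")
  check_number(choice_noise, "choice_noise", min = 0)
  check_number(trait_correlation, "trait_correlation", min = -1, max = 1)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_calibration = as.integer(n_calibration),
    n_checking = as.integer(n_checking),
    n_implicit_pairs = as.integer(n_implicit_pairs),
    n_explicit = as.integer(n_explicit),
    m1 = m1, m2 = m2, questionnaires = questionnaires,
    sensitivity_mean = sensitivity_mean, sensitivity_sd = sensitivity_sd,
    meta_noise_mean = meta_noise_mean, meta_noise_sd = meta_noise_sd,
    confidence_thresholds = confidence_thresholds,
    choice_noise = choice_noise,
    trait_correlation = trait_correlation,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a subject profile
#'
#' The generative traits of one simulated observer: perceptual sensitivity,
#' meta-noise, confidence cutpoints, checking-policy offset, questionnaire
#' scores and standardized trait covariates.
#'
#' @param subject_id Identifier.
#' @param sensitivity_k Evidence units per unit coherence (> 0).
#' @param meta_noise_sigma SD of the second-order readout noise (>= 0).
#' @param confidence_thresholds Five strictly increasing cutpoints.
#' @param random_intercept_m1 Subject-level log-rate offset of the checking
#'   policy.
#' @param padua_score,mistrust_score Questionnaire totals (instrument range).
#' @param trait_mratio,trait_cmi Standardized trait covariates.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            sensitivity_k,
                            meta_noise_sigma,
                            confidence_thresholds = c(0.5, 1.0, 1.5, 2.0, 2.5),
                            random_intercept_m1 = 0,
                            padua_score = NA_real_,
                            mistrust_score = NA_real_,
                            trait_mratio = 0,
                            trait_cmi = 0) {
  check_number(sensitivity_k, "sensitivity_k")
  if (sensitivity_k <= 0) abort_input("sensitivity_k must be > 0")
  check_number(meta_noise_sigma, "meta_noise_sigma", min = 0)
  if (length(confidence_thresholds) != 5L || any(diff(confidence_thresholds) <= 0))
    abort_input("confidence_thresholds must be 5 strictly increasing cutpoints")
  qd <- questionnaire_defaults()
  if (!is.na(padua_score) &&
      (padua_score < qd$padua$min || padua_score > qd$padua$max))
    abort_input("padua_score outside instrument range [%g, %g]",
                qd$padua$min, qd$padua$max)
  if (!is.na(mistrust_score) &&
      (mistrust_score < qd$mistrust$min || mistrust_score > qd$mistrust$max))
    abort_input("mistrust_score outside instrument range [%g, %g]",
                qd$mistrust$min, qd$mistrust$max)
  structure(list(
    subject_id = subject_id,
    sensitivity_k = sensitivity_k,
    meta_noise_sigma = meta_noise_sigma,
    confidence_thresholds = confidence_thresholds,
    random_intercept_m1 = random_intercept_m1,
    padua_score = padua_score,
    mistrust_score = mistrust_score,
    trait_mratio = trait_mratio,
    trait_cmi = trait_cmi
  ), class = "subject_profile")
}
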
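# Synthetic-cohort generators: observer mechanics, checking policy,
# accuracy model, questionnaires, determinism.

test_that("fixed seed gives byte-identical cohorts", {
  cfg <- cohort_config(n_subjects = 4, n_checking = 30, n_implicit_pairs = 20,
                       n_explicit = 20, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
  g1 <- simulate_glmm_cohort(cfg, n_trials = 25)
  g2 <- simulate_glmm_cohort(cfg, n_trials = 25)
  expect_identical(g1, g2)
})

test_that("observer accuracy follows the probit of scaled coherence", {
  pr <- subject_profile(1, sensitivity_k = 5.2, meta_noise_sigma = 0.5)
  # no signal -> chance
  t0 <- simulate_observer_trials(pr, rep(0, 20000), seed = 1)
  expect_lt(abs(mean(t0$correct) - 0.5), 3 * sqrt(0.25 / 20000))
  # accuracy ~ pnorm(k * c) within binomial error at several coherences
  for (c0 in c(0.05, 0.15, 0.3)) {
    tr <- simulate_observer_trials(pr, rep(c0, 40000), seed = round(100 * c0))
    p <- pnorm(5.2 * c0)
    expect_lt(abs(mean(tr$correct) - p), 4 * sqrt(p * (1 - p) / 40000))
  }
  # sensitivity tuned for 70% at a target coherence delivers ~70%
  c_target <- 0.12
  k <- qnorm(0.70) / c_target
  pr70 <- subject_profile(2, sensitivity_k = k, meta_noise_sigma = 0.5)
  tr <- simulate_observer_trials(pr70, rep(c_target, 40000), seed = 3)
  expect_lt(abs(mean(tr$correct) - 0.70), 0.01)
})

test_that("invalid observer inputs are rejected", {
  pr <- subject_profile(1, sensitivity_k = 5, meta_noise_sigma = 0.5)
  expect_error(simulate_observer_trial(pr, -0.1), "coherence")
  expect_error(simulate_observer_trials(pr, 0.5, task = "unknown"), "task")
  expect_error(subject_profile(1, sensitivity_k = -1, meta_noise_sigma = 0),
               "sensitivity_k")
  expect_error(subject_profile(1, 5, 0.5, confidence_thresholds = c(1, 2, 3, 3, 4)),
               "increasing")
})

test_that("implicit pairs have exactly one chosen trial and ordered accuracy", {
  pr <- subject_profile(1, sensitivity_k = 5.2, meta_noise_sigma = 0.3)
  coh <- rep(0.15, 20000)
  imp <- simulate_implicit_pairs(pr, coh, coh, choice_noise = 0, seed = 4)
  expect_true(all(tapply(imp$chosen, imp$pair_id, sum) == 1))
  acc_chosen <- mean(imp$correct[imp$chosen])
  acc_disc <- mean(imp$correct[!imp$chosen])
  expect_gt(acc_chosen, acc_disc + 0.02)
  # random chooser: no accuracy gap beyond noise
  rnd <- simulate_implicit_pairs(pr, coh, coh, choice_noise = Inf, seed = 5)
  gap <- mean(rnd$correct[rnd$chosen]) - mean(rnd$correct[!rnd$chosen])
  expect_lt(abs(gap), 0.015)
})

test_that("checking counts match Poisson and lognormal-Poisson closed forms", {
  cf <- m1_coefficients()
  cf$difficulty <- cf$mratio_difficulty <- cf$cmi_difficulty <- 0
  cf$padua_difficulty <- cf$mistrust_difficulty <- 0
  # many subjects: the marginal-mean error is dominated by between-subject
  # variance, not the trial count
  des <- data.frame(subject_id = rep(1:10000, each = 10), difficulty = 0,
                    mratio = 0, cmi = 0, padua = 0, mistrust = 0)
  # homogeneous: all variances zero
  cf0 <- cf; cf0$subject_sd <- 0; cf0$olre_sd <- 0; cf0$intercept <- log(0.8)
  d0 <- simulate_checking_counts(des, cf0, seed = 6)
  expect_lt(abs(mean(d0$n_checks) - 0.8) / 0.8, 0.02)
  # mixed: E[count] = exp(b0 + (tau^2 + sigma^2)/2)
  d1 <- simulate_checking_counts(des, cf, seed = 7)
  m_closed <- exp(cf$intercept + (cf$subject_sd^2 + cf$olre_sd^2) / 2)
  expect_lt(abs(mean(d1$n_checks) - m_closed) / m_closed, 0.02)
  # counts increase with difficulty under the default slope
  set.seed(80)
  des$difficulty <- rnorm(nrow(des))
  d2 <- simulate_checking_counts(des, m1_coefficients(), seed = 8)
  terc <- cut(d2$difficulty, quantile(d2$difficulty, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = 1:3)
  means <- tapply(d2$n_checks, terc, mean)
  expect_true(all(diff(means) > 0))
  # non-finite coefficients are named
  cfbad <- cf; cfbad$intercept <- Inf
  expect_error(simulate_checking_counts(des, cfbad), "intercept")
})

test_that("accuracy generator reduces to chance and recovers its GLM truth", {
  cf <- m2_coefficients()
  for (nm in setdiff(names(cf), "subject_sd")) cf[[nm]] <- 0
  cf$subject_sd <- 0
  set.seed(81)
  des <- data.frame(subject_id = 1, difficulty = rnorm(20000), mratio = 0,
                    cmi = 0, padua = 0, mistrust = 0, n_checks = rpois(20000, 1))
  d0 <- simulate_accuracy(des, cf, seed = 9)
  expect_lt(abs(mean(d0$correct) - 0.5), 0.015)
  expect_error(simulate_accuracy(des[, setdiff(names(des), "n_checks")], cf),
               "n_checks")
  # one subject, zero random variance: plain logistic GLM recovers the slopes
  cf2 <- m2_coefficients(); cf2$subject_sd <- 0
  d1 <- simulate_accuracy(des, cf2, seed = 10)
  g <- glm(correct ~ difficulty + checks_z + difficulty:checks_z,
           binomial, data = d1)
  ci <- suppressMessages(confint(g))
  expect_gt(cf2$difficulty, ci["difficulty", 1])
  expect_lt(cf2$difficulty, ci["difficulty", 2])
  expect_gt(cf2$checks, ci["checks_z", 1])
  expect_lt(cf2$checks, ci["checks_z", 2])
  expect_gt(cf2$checks_difficulty, ci["difficulty:checks_z", 1])
  expect_lt(cf2$checks_difficulty, ci["difficulty:checks_z", 2])
})

test_that("questionnaire draws match configured moments and ranges", {
  q <- questionnaire_defaults()
  padua <- sample_questionnaires(10000, q$padua, seed = 11)
  expect_lt(abs(mean(padua) - 57.6), 1.2)
  expect_lt(abs(sd(padua) - 28.8), 1.2)
  expect_true(all(padua >= 0 & padua <= 240))
  mistrust <- sample_questionnaires(10000, q$mistrust, seed = 12)
  expect_lt(abs(mean(mistrust) - 20.5), 0.4)
  expect_true(all(mistrust >= 10 & mistrust <= 40))
  # degenerate SD: every score is the rounded mean
  const <- sample_questionnaires(50, list(mean = 57.6, sd = 0, min = 0, max = 240),
                                 seed = 13)
  expect_true(all(const == 58L))
  expect_error(sample_questionnaires(5, list(mean = 1, sd = -1, min = 0, max = 2)),
               "sd")
})

test_that("cohort CSV and config sidecar round-trip", {
  cfg <- cohort_config(n_subjects = 3, n_checking = 15, n_implicit_pairs = 10,
                       n_explicit = 10, seed = 14)
  co <- simulate_cohort(cfg)
  path <- file.path(tempdir(), "cohort_test.csv")
  paths <- write_cohort(co, cfg, path)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_equal(nrow(back), nrow(co$trials))
  side <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(side$seed, 14)
  expect_equal(side$n_subjects, 3)
  unlink(paths)
})
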
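# Rating tables, meta-d'/M-ratio, type-2 ROC and the confidence modulation
# index.

make_explicit <- function(k, sigma, n, seed, coh = 0.2) {
  pr <- subject_profile(1, sensitivity_k = k, meta_noise_sigma = sigma)
  simulate_observer_trials(pr, rep(coh, n), "explicit", seed = seed)
}

test_that("rating tables cross-tabulate exactly and invariantly", {
  tr <- data.frame(direction = 1, response = 1, confidence = 6)[rep(1, 10), ]
  tab <- build_rating_table(tr)
  expect_equal(sum(tab), 10)
  expect_equal(tab["1", "1", "6"], 10L)
  tr2 <- make_explicit(5, 0.5, 500, seed = 1)
  t_a <- build_rating_table(tr2)
  t_b <- build_rating_table(tr2[sample(nrow(tr2)), ])
  expect_identical(t_a, t_b)
  tr2$confidence[3] <- NA
  expect_error(build_rating_table(tr2), "rows: 3")
})

test_that("simulated rating tables match the closed-form SDT probabilities", {
  k <- 5; coh <- 0.2; sigma <- 0.5; n <- 100000
  tr <- make_explicit(k, sigma, n, seed = 2, coh = coh)
  tab <- build_rating_table(tr)
  probs <- sdt_rating_probs(k * coh, sigma, c(0.5, 1.0, 1.5, 2.0, 2.5))
  # each cell within 5 multinomial SDs (cells are (stim, resp, rating)/2 since
  # stimulus is equiprobable)
  p_cell <- probs / 2
  obs <- as.numeric(tab) / n
  tol <- 5 * sqrt(pmax(p_cell, 1e-6) * (1 - p_cell) / n)
  expect_true(all(abs(obs - as.numeric(p_cell)) < tol + 2e-4))
})

test_that("meta-d' equals d' for an ideal observer and 0 for shuffled ratings", {
  tr <- make_explicit(5.2, 0, 100000, seed = 3)
  md <- fit_meta_d(build_rating_table(tr))
  expect_lt(abs(md$m_ratio - 1), 0.08)
  set.seed(4)
  tr$confidence <- sample(tr$confidence)
  md0 <- fit_meta_d(build_rating_table(tr))
  expect_lt(abs(md0$meta_d), 0.1)
})

test_that("optimizer matches dense grid search on a binary-confidence table", {
  set.seed(5)
  pr <- subject_profile(1, sensitivity_k = 5, meta_noise_sigma = 0.7,
                        confidence_thresholds = c(-1, -0.5, 1.1, 3, 4))
  tr <- simulate_observer_trials(pr, rep(0.25, 3000), "explicit", seed = 5)
  tr$confidence <- ifelse(tr$confidence >= 3, 2L, 1L) # collapse to 2 levels
  tab <- build_rating_table(tr, n_ratings = 2L)
  fit <- fit_meta_d(tab)
  oracle <- meta_d_grid_fit(tab)
  expect_lt(abs(fit$meta_d - oracle$meta_d), 0.02)
  expect_lte(-fit$logLik, oracle$nll + 0.01)
})

test_that("M-ratio is scale invariant and bounded by d' under added noise", {
  tr <- make_explicit(5, 0.6, 20000, seed = 6)
  tab <- build_rating_table(tr)
  f1 <- fit_meta_d(tab)
  tab7 <- structure(tab * 7L, class = "rating_table")
  f7 <- fit_meta_d(tab7)
  expect_lt(abs(f1$m_ratio - f7$m_ratio), 0.02)
  # confidence = decision evidence + independent noise cannot beat d'
  mr <- vapply(c(0.2, 0.6, 1.2), function(s) {
    f <- fit_meta_d(build_rating_table(make_explicit(5, s, 30000, seed = 70 + s * 10)))
    f$m_ratio
  }, numeric(1))
  expect_true(all(mr < 1 + 0.1))
  expect_true(all(diff(mr) < 0)) # and decreases with meta-noise
})

test_that("negative d' is flagged undefined, never divided", {
  tr <- make_explicit(5, 0.5, 2000, seed = 8)
  tr$response <- -tr$response # systematically wrong observer
  md <- fit_meta_d(build_rating_table(tr))
  expect_false(md$defined)
  expect_true(is.na(md$m_ratio))
})

test_that("type-2 ROC has proper endpoints and tracks meta-noise", {
  tr <- make_explicit(5, 0.4, 20000, seed = 9)
  tab <- build_rating_table(tr)
  roc <- type2_roc(tab)
  for (curve in list(roc$type1, roc$type2)) {
    expect_equal(curve$far[1], 0); expect_equal(curve$hr[1], 0)
    expect_equal(tail(curve$far, 1), 1); expect_equal(tail(curve$hr, 1), 1)
    expect_true(all(diff(curve$far) >= 0) && all(diff(curve$hr) >= 0))
  }
  # uninformative confidence: diagonal
  set.seed(10)
  tru <- tr; tru$confidence <- sample(6, nrow(tr), TRUE)
  expect_lt(abs(type2_roc(build_rating_table(tru))$auc2 - 0.5), 0.02)
  # perfect confidence: through (0, 1)
  trp <- tr; trp$confidence <- ifelse(trp$correct == 1, 6L, 1L)
  expect_gt(type2_roc(build_rating_table(trp))$auc2, 0.99)
  # AUC decreases with meta-noise
  aucs <- vapply(c(0.1, 0.5, 1.5), function(s)
    type2_roc(build_rating_table(make_explicit(5, s, 30000, seed = 90 + s * 10)))$auc2,
    numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("CMI is antisymmetric and matches an independent simulation oracle", {
  pr <- subject_profile(1, sensitivity_k = 5.2, meta_noise_sigma = 0.3)
  set.seed(11)
  coh_a <- runif(30000, 0.05, 0.45); coh_b <- runif(30000, 0.05, 0.45)
  imp <- simulate_implicit_pairs(pr, coh_a, coh_b, choice_noise = 0, seed = 11)
  est <- compute_cmi(imp)
  expect_true(est$defined)
  expect_gt(est$cmi, 0)
  # exact antisymmetry under label swap
  swapped <- imp; swapped$chosen <- !swapped$chosen
  est2 <- compute_cmi(swapped)
  expect_equal(est2$cmi, -est$cmi, tolerance = 1e-10)
  # independent oracle: re-simulate the task with plain code + grid MLE slopes
  oracle <- simulate_cfc_oracle(5.2, 0.3, coh_a, coh_b, seed = 12)
  expect_lt(abs(est$cmi - oracle), 0.08)
})

test_that("pairing structure is validated", {
  bad <- data.frame(pair_id = c(1, 1, 1), chosen = c(TRUE, FALSE, FALSE),
                    coherence = 0.2, correct = 1)
  expect_error(compute_cmi(bad), "exactly two")
  bad2 <- data.frame(pair_id = c(1, 1), chosen = c(TRUE, TRUE),
                     coherence = c(0.2, 0.3), correct = c(1, 0))
  expect_error(compute_cmi(bad2), "exactly one chosen")
})

test_that("rating tables serialize to CSV", {
  tr <- make_explicit(5, 0.5, 300, seed = 13)
  tab <- build_rating_table(tr)
  p <- file.path(tempdir(), "ratings.csv")
  write_rating_table(tab, p)
  back <- read.csv(p)
  expect_equal(nrow(back), 2)
  expect_equal(sum(back[, -1]), sum(tab))
  unlink(p)
})
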
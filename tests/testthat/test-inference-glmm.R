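# Mixed-model machinery: spec validation, GLM reductions, the Laplace
# objective against exact quadrature, Wald/LRT, bootstrap CIs.

glm_spec <- function(family = "poisson", fixed = "x")
  model_spec("y", fixed = fixed, family = family, subject = NULL,
             standardize = FALSE)

test_that("model specs are validated", {
  expect_error(model_spec("y", fixed = "a", interactions = "a:b",
                          family = "poisson"), "declared main effects")
  expect_error(model_spec("y", fixed = "a", family = "binomial", olre = TRUE),
               "poisson")
  expect_error(fit_glmm(model_spec("y", fixed = "x", family = "poisson",
                                   subject = "sid"),
                        data.frame(y = rpois(5, 1), x = rnorm(5), sid = 1)),
               "2 subjects")
})

test_that("intercept-only Poisson reduces to the closed form", {
  set.seed(1)
  d <- data.frame(y = rpois(500, 2.3))
  f <- fit_glmm(model_spec("y", fixed = character(0), family = "poisson",
                           subject = NULL), d)
  expect_equal(f$coefficients$b[1], log(mean(d$y)), tolerance = 1e-10)
})

test_that("variances fixed at zero reproduce the plain GLM exactly", {
  set.seed(2)
  d <- data.frame(sid = rep(1:6, each = 50), x = rnorm(300))
  d$y <- rpois(300, exp(0.4 + 0.3 * d$x))
  sp <- model_spec("y", fixed = "x", family = "poisson", subject = "sid",
                   olre = TRUE, standardize = FALSE)
  f0 <- fit_glmm(sp, d, fix_variance = 0)
  g <- glm(y ~ x, poisson, d)
  expect_equal(f0$coefficients$b, unname(coef(g)), tolerance = 1e-9)
  expect_equal(f0$logLik, as.numeric(logLik(g)), tolerance = 1e-9)
})

test_that("Laplace objective matches the quadrature oracle on fixtures", {
  for (fx in laplace_fixtures()) {
    la <- laplace_loglik(fx$spec, fx$data, fx$beta, fx$subject_sd, fx$olre_sd)
    qu <- quadrature_loglik(fx$spec, fx$data, fx$beta, fx$subject_sd,
                            fx$olre_sd, nodes = 40)
    expect_lt(abs(la - qu) / abs(qu), 1e-4)
  }
})

test_that("the fitted model's log-likelihood equals the Laplace objective", {
  set.seed(3)
  d <- data.frame(sid = rep(1:20, each = 10), x = rnorm(200))
  u <- rnorm(20, 0, 0.5)
  d$y <- rpois(200, exp(1 + 0.3 * d$x + u[d$sid] + rnorm(200, 0, 0.3)))
  sp <- model_spec("y", fixed = "x", family = "poisson", subject = "sid",
                   olre = TRUE, standardize = FALSE)
  f <- fit_glmm(sp, d)
  la <- laplace_loglik(sp, d, f$coefficients$b, f$varcomp[["subject_sd"]],
                       f$varcomp[["olre_sd"]])
  expect_lt(abs(f$logLik - la) / abs(la), 1e-4)
})

test_that("Wald machinery behaves and agrees asymptotically with the LRT", {
  tab <- wald_table(structure(list(
    coefficients = data.frame(term = c("a", "b"), b = c(0, 1),
                              se = c(0.5, 0), z = NA, p = NA),
    converged = TRUE), class = "mixed_fit"))
  expect_equal(tab$p[1], 1)
  expect_true(is.na(tab$z[2]) && is.na(tab$p[2]))
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  # single-coefficient Wald vs LRT on a well-powered GLM
  set.seed(4)
  d <- data.frame(x = rnorm(4000), w = rnorm(4000))
  d$y <- rpois(4000, exp(0.3 + 0.05 * d$x))
  f <- fit_glmm(glm_spec(fixed = c("x", "w")), d)
  p_wald <- f$coefficients$p[f$coefficients$term == "x"]
  g_full <- glm(y ~ x + w, poisson, d); g_red <- glm(y ~ w, poisson, d)
  p_lrt <- pchisq(2 * (logLik(g_full) - logLik(g_red)), 1, lower.tail = FALSE)
  expect_lt(abs(p_wald - p_lrt) / p_lrt, 0.2)
})

test_that("equality-constrained LRT is symmetric, null-calibrated and exact on ties", {
  sp <- model_spec("y", fixed = c("a", "b", "z"),
                   interactions = c("a:z", "b:z"), family = "poisson",
                   subject = NULL, standardize = FALSE)
  set.seed(5)
  d <- data.frame(a = rnorm(1500), b = rnorm(1500), z = rnorm(1500))
  d$y <- rpois(1500, exp(0.2 + 0.25 * d$a * d$z + 0.1 * d$b * d$z))
  lr_ab <- lrt_equal_coefficients(sp, d, "a:z", "b:z")
  lr_ba <- lrt_equal_coefficients(sp, d, "b:z", "a:z")
  expect_equal(unname(lr_ab$statistic), unname(lr_ba$statistic),
               tolerance = 1e-8)
  expect_error(lrt_equal_coefficients(sp, d, "a:z", "q:z"), "spec")
  # identical columns -> statistic 0, p 1
  d2 <- d; d2$b <- d2$a
  lr0 <- suppressWarnings(lrt_equal_coefficients(sp, d2, "a:z", "b:z"))
  expect_lt(unname(lr0$statistic), 1e-6)
  expect_equal(lr0$p_value, 1)
  # type-I error under truly equal coefficients
  set.seed(6)
  rej <- mean(replicate(500, {
    dd <- data.frame(a = rnorm(400), b = rnorm(400), z = rnorm(400))
    dd$y <- rpois(400, exp(0.2 + 0.15 * dd$a * dd$z + 0.15 * dd$b * dd$z))
    lrt_equal_coefficients(sp, dd, "a:z", "b:z")$p_value < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("parametric bootstrap is reproducible, covers, and shrinks with n", {
  set.seed(7)
  d <- data.frame(x = rnorm(400)); d$y <- rpois(400, exp(0.5 + 0.4 * d$x))
  f <- fit_glmm(glm_spec(), d)
  ci1 <- parametric_bootstrap_ci(f, n_boot = 200, seed = 11)
  ci2 <- parametric_bootstrap_ci(f, n_boot = 200, seed = 11)
  expect_identical(ci1, ci2)
  # coverage of the generating slope over outer replicates
  set.seed(8)
  cover <- mean(replicate(60, {
    dd <- data.frame(x = rnorm(250)); dd$y <- rpois(250, exp(0.5 + 0.4 * dd$x))
    ff <- fit_glmm(glm_spec(), dd)
    ci <- parametric_bootstrap_ci(ff, n_boot = 200, seed = 12)
    ci$ci_low[2] <= 0.4 && 0.4 <= ci$ci_high[2]
  }))
  expect_gte(cover, 0.85)
  # width ~ 1/sqrt(n): factor-2 check at 4n
  set.seed(9)
  d4 <- data.frame(x = rnorm(1600)); d4$y <- rpois(1600, exp(0.5 + 0.4 * d4$x))
  f4 <- fit_glmm(glm_spec(), d4)
  ci4 <- parametric_bootstrap_ci(f4, n_boot = 200, seed = 13)
  w1 <- ci1$ci_high[2] - ci1$ci_low[2]
  w4 <- ci4$ci_high[2] - ci4$ci_low[2]
  expect_lt(abs(w1 / w4 - 2), 0.7)
})

test_that("printed generating coefficients are recovered at reduced scale", {
  # scaled-down analogue of the full recovery run (the acceptance suite does
  # 100 x 100): 6 replicates of 40 subjects x 40 trials, Wald 95% CIs
  printed_m1 <- c(difficulty = 0.90, mratio.x.difficulty = 0.08,
                  cmi.x.difficulty = -0.05, padua.x.difficulty = 0.10,
                  mistrust.x.difficulty = -0.09)
  printed_m2 <- c(checks = -0.26, checks.x.difficulty = 0.20)
  hits <- 0; total <- 0
  for (s in 1:6) {
    d <- simulate_glmm_cohort(cohort_config(n_subjects = 40, seed = 500 + s),
                              n_trials = 40)
    d$checks <- d$n_checks
    f1 <- fit_glmm(m1_spec(), d)
    f2 <- fit_glmm(m2_spec(), d)
    for (fit in list(list(f = f1, truth = printed_m1),
                     list(f = f2, truth = printed_m2))) {
      tab <- fit$f$coefficients
      for (nm in names(fit$truth)) {
        i <- match(nm, tab$term)
        total <- total + 1
        hits <- hits + (tab$b[i] - 1.96 * tab$se[i] <= fit$truth[[nm]] &&
                          fit$truth[[nm]] <= tab$b[i] + 1.96 * tab$se[i])
      }
    }
  }
  expect_gte(hits / total, 0.9)
})
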
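# Mixed-effects models of checking and accuracy.
#
# The checking-count model is a Poisson GLMM with a subject random intercept
# and an observation-level random effect (OLRE) absorbing overdispersion; the
# accuracy model is a logistic GLMM with a subject random intercept. Both are
# fit by maximum likelihood with a Laplace approximation over the latent
# vector (lme4's nested/sparse Laplace machinery). An independent Laplace
# objective and a brute-force Gauss-Hermite quadrature oracle are provided so
# the approximation itself can be validated on small instances.

#' Specify a mixed model
#'
#' @param outcome Outcome column name.
#' @param fixed Character vector of main-effect columns.
#' @param interactions Character vector of `"a:b"` interaction terms; both
#'   sides must be declared main effects.
#' @param family `"poisson"` (log link) or `"binomial"` (logit link).
#' @param subject Grouping column for the subject random intercept, or `NULL`
#'   for a fixed-effects-only model.
#' @param olre Add an observation-level random intercept (Poisson only).
#' @param standardize Standardize the main-effect predictors (interactions
#'   are then products of standardized mains).
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome, fixed, interactions = character(0),
                       family = c("poisson", "binomial"),
                       subject = "subject_id", olre = FALSE,
                       standardize = TRUE) {
  family <- match.arg(family)
  for (tm in interactions) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% fixed))
      abort_input("interaction `%s` must combine two declared main effects", tm)
  }
  if (olre && family != "poisson")
    abort_input("observation-level random effects are only used with the poisson family")
  structure(list(outcome = outcome, fixed = fixed, interactions = interactions,
                 family = family, subject = subject, olre = olre,
                 standardize = standardize), class = "model_spec")
}

#' Default checking-count model specification
#' @return A `model_spec` for the Poisson checking model (subject intercept +
#'   OLRE, difficulty and trait predictors with trait-by-difficulty
#'   interactions).
#' @export
m1_spec <- function() {
  model_spec(
    outcome = "n_checks",
    fixed = c("difficulty", "mratio", "cmi", "padua", "mistrust"),
    interactions = c("mratio:difficulty", "cmi:difficulty",
                     "padua:difficulty", "mistrust:difficulty"),
    family = "poisson", subject = "subject_id", olre = TRUE
  )
}

#' Default accuracy model specification
#' @return A `model_spec` for the logistic accuracy model (subject intercept,
#'   difficulty, checks, checks-by-difficulty, traits and trait-by-checks
#'   interactions).
#' @export
m2_spec <- function() {
  model_spec(
    outcome = "correct",
    fixed = c("difficulty", "checks", "mratio", "cmi", "padua", "mistrust"),
    interactions = c("checks:difficulty", "mratio:checks", "cmi:checks",
                     "padua:checks", "mistrust:checks"),
    family = "binomial", subject = "subject_id", olre = FALSE
  )
}

# Standardize mains and materialize interaction product columns. Interaction
# "a:b" becomes an explicit column "a.x.b" so equality-constrained restricted
# models can literally replace two columns by their sum.
prepare_design <- function(spec, data) {
  check_columns(data, c(spec$outcome, spec$fixed,
                        if (!is.null(spec$subject)) spec$subject))
  scaling <- NULL
  if (spec$standardize) {
    std <- standardize_predictors(data, spec$fixed)
    data <- std$data
    scaling <- std$scaling
  }
  int_cols <- character(0)
  for (tm in spec$interactions) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    cn <- paste(parts, collapse = ".x.")
    data[[cn]] <- data[[parts[1]]] * data[[parts[2]]]
    int_cols <- c(int_cols, cn)
  }
  terms <- c(spec$fixed, int_cols)
  list(data = data, terms = terms, int_cols = int_cols, scaling = scaling)
}

glmm_formula <- function(spec, terms) {
  if (!length(terms)) terms <- "1"
  rhs <- paste(c(terms, if (!is.null(spec$subject))
    sprintf("(1 | %s)", spec$subject),
    if (spec$olre) "(1 | .obs)"), collapse = " + ")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

#' Fit a mixed-effects model
#'
#' Fits the specified GLMM by Laplace-approximate maximum likelihood
#' (`lme4::glmer`); with no random terms the model reduces exactly to a GLM
#' and is fit with `stats::glm`, which is also the meaning of
#' `fix_variance = 0`. Non-convergence is reported in the returned object,
#' never silently dropped.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with outcome, covariates and grouping column.
#' @param fix_variance If 0, constrain all random-effect variances to zero
#'   (plain GLM on the same design). `NULL` (default) estimates them.
#' @param optimizer Passed to `lme4::glmerControl` (default `"bobyqa"`, which
#'   is robust for high-dimensional OLRE models).
#' @return A `mixed_fit`: `coefficients` table (term, b, se, z, p),
#'   `varcomp`, `logLik`, `vif`, `converged`, `messages`, the underlying
#'   `model`, and the prepared `data`.
#' @export
fit_glmm <- function(spec, data, fix_variance = NULL, optimizer = "bobyqa") {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_design(spec, data)
  d <- prep$data
  no_random <- is.null(spec$subject) && !spec$olre
  drop_random <- !is.null(fix_variance) && all(fix_variance == 0)
  if (!no_random && !drop_random) {
    if (length(unique(d[[spec$subject]])) < 2L)
      abort_input("need >= 2 subjects to estimate a subject random intercept")
  }
  if (spec$olre) d$.obs <- factor(seq_len(nrow(d)))
  messages <- character(0)
  if (no_random || drop_random) {
    f <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(c(prep$terms, "1"), collapse = " + ")))
    model <- stats::glm(f, family = spec$family, data = d)
    b <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    converged <- model$converged
    varcomp <- c(subject_sd = 0, olre_sd = if (spec$olre) 0 else NA_real_)
    ll <- as.numeric(stats::logLik(model))
  } else {
    f <- glmm_formula(spec, prep$terms)
    model <- withCallingHandlers(
      lme4::glmer(f, family = spec$family, data = d,
                  control = lme4::glmerControl(optimizer = optimizer,
                                               calc.derivs = FALSE)),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    b <- lme4::fixef(model)
    se <- sqrt(Matrix::diag(stats::vcov(model)))
    converged <- length(model@optinfo$conv$lme4) == 0 &&
      model@optinfo$conv$opt == 0
    vc <- lme4::VarCorr(model)
    sds <- vapply(vc, function(v) attr(v, "stddev")[[1]], numeric(1))
    varcomp <- c(subject_sd = unname(sds[spec$subject]),
                 olre_sd = if (spec$olre) unname(sds[".obs"]) else NA_real_)
    ll <- as.numeric(stats::logLik(model))
  }
  z <- b / se
  coefficients <- data.frame(
    term = names(b), b = unname(b), se = unname(se), z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))), row.names = NULL
  )
  X <- as.matrix(d[, prep$terms, drop = FALSE])
  # VIF is a diagnostic: an aliased design is reported (NA), not fatal here;
  # call vif() directly to get the hard rank-deficiency error.
  vifs <- if (!length(prep$terms)) numeric(0)
  else tryCatch(vif(X), error = function(e)
    structure(rep(NA_real_, length(prep$terms)),
              names = prep$terms, message = conditionMessage(e)))
  structure(list(spec = spec, coefficients = coefficients, varcomp = varcomp,
                 logLik = ll, vif = vifs, converged = converged,
                 messages = messages, boundary = any(varcomp == 0, na.rm = TRUE) &&
                   !(no_random || drop_random),
                 model = model, data = d, terms = prep$terms,
                 scaling = prep$scaling),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, digits = 3, ...) {
  fam <- x$spec$family
  cat(sprintf("%s mixed model: %s ~ %s\n", fam, x$spec$outcome,
              paste(x$terms, collapse = " + ")))
  cat(sprintf("  random: %s%s | logLik = %.2f%s\n",
              x$spec$subject %||% "none",
              if (x$spec$olre) " + OLRE" else "", x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- cbind(term = x$coefficients$term,
               round(x$coefficients[, c("b", "se", "z")], digits),
               p = signif(x$coefficients$p, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Wald coefficient table
#'
#' `z = b / SE`, two-sided `p = 2 * pnorm(-|z|)`. Coefficients with zero SE
#' are flagged `NA` rather than reported as infinite.
#'
#' @param fit A [fit_glmm()] result.
#' @return Data frame with columns `term`, `b`, `se`, `z`, `p`.
#' @export
wald_table <- function(fit) {
  if (!fit$converged)
    warning("Wald table from a non-converged fit", call. = FALSE)
  tab <- fit$coefficients
  zero <- !is.finite(tab$se) | tab$se <= 0
  tab$z[zero] <- NA_real_
  tab$p[zero] <- NA_real_
  tab$z[!zero] <- tab$b[!zero] / tab$se[!zero]
  tab$p[!zero] <- 2 * stats::pnorm(-abs(tab$z[!zero]))
  tab
}

#' Likelihood-ratio test of coefficient equality
#'
#' Compares the full model against a restricted model in which the design
#' columns of `term_a` and `term_b` are replaced by their sum, which forces
#' the two regression coefficients to be equal. The statistic is
#' `2 (logLik_full - logLik_restricted)` on 1 df.
#'
#' @param spec A [model_spec()] containing both terms.
#' @param data The data.
#' @param term_a,term_b Term names as in the spec (e.g.
#'   `"mratio:difficulty"`).
#' @param fits Optional pre-computed full fit (to avoid refitting).
#' @return A `test_result` with the chi-square statistic, `df = 1`, `p_value`
#'   and both fits in `$fits`.
#' @export
lrt_equal_coefficients <- function(spec, data, term_a, term_b, fits = NULL) {
  all_terms <- c(spec$fixed, spec$interactions)
  if (!all(c(term_a, term_b) %in% all_terms))
    abort_input("both terms must appear in the model spec")
  full <- fits %||% fit_glmm(spec, data)
  col_of <- function(tm) if (grepl(":", tm))
    paste(strsplit(tm, ":")[[1]], collapse = ".x.") else tm
  ca <- col_of(term_a); cb <- col_of(term_b)
  d <- full$data
  d$.constrained <- d[[ca]] + d[[cb]]
  terms_r <- c(setdiff(full$terms, c(ca, cb)), ".constrained")
  if (is.null(full$spec$subject) && !full$spec$olre) {
    f <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(terms_r, collapse = " + ")))
    mr <- stats::glm(f, family = spec$family, data = d)
    ll_r <- as.numeric(stats::logLik(mr))
  } else {
    f <- glmm_formula(spec, terms_r)
    mr <- suppressWarnings(
      lme4::glmer(f, family = spec$family, data = d,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE)))
    ll_r <- as.numeric(stats::logLik(mr))
  }
  stat <- 2 * (full$logLik - ll_r)
  if (stat < -1e-4)
    abort_input("restricted log-likelihood exceeds full (%.4g); convergence failure",
                stat)
  stat <- max(stat, 0)
  structure(list(statistic = c(chisq = stat), df = 1,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 method = "lrt", tails = 1,
                 fits = list(full = full, restricted = mr)),
            class = "test_result")
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` outcome vectors from the fitted model, refits, and
#' takes percentile 2.5/97.5 bounds per fixed-effect coefficient. Errors if
#' more than 10% of the refits fail.
#'
#' @param fit A converged [fit_glmm()] result.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed for the simulation stream.
#' @param level Confidence level (default 0.95).
#' @return Data frame `term`, `ci_low`, `ci_high`, plus attribute
#'   `"n_failed"`.
#' @export
parametric_bootstrap_ci <- function(fit, n_boot = 1000, seed = 1L,
                                    level = 0.95) {
  if (!fit$converged) abort_input("bootstrap requires a converged fit")
  model <- fit$model
  is_mer <- inherits(model, "merMod")
  with_seed(seed, {
    sims <- stats::simulate(model, nsim = n_boot)
    est <- matrix(NA_real_, n_boot, nrow(fit$coefficients))
    for (i in seq_len(n_boot)) {
      refit_i <- if (is_mer) {
        try(suppressMessages(suppressWarnings(
          lme4::refit(model, newresp = sims[[i]]))), silent = TRUE)
      } else {
        d2 <- fit$data
        d2[[fit$spec$outcome]] <- sims[[i]]
        try(suppressWarnings(
          stats::glm(stats::formula(model), family = fit$spec$family,
                     data = d2)), silent = TRUE)
      }
      if (!inherits(refit_i, "try-error")) {
        b <- if (is_mer) lme4::fixef(refit_i) else stats::coef(refit_i)
        if (length(b) == ncol(est)) est[i, ] <- b
      }
    }
    n_failed <- sum(!stats::complete.cases(est))
    if (n_failed > 0.1 * n_boot)
      abort_input("%d of %d bootstrap refits failed", n_failed, n_boot)
    a <- (1 - level) / 2
    ci <- t(apply(est, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
    out <- data.frame(term = fit$coefficients$term,
                      ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL)
    attr(out, "n_failed") <- n_failed
    out
  })
}

# --- Independent Laplace objective and quadrature oracle -------------------

family_loglik <- function(family) {
  switch(family,
    poisson = list(
      ll = function(y, eta) y * eta - exp(eta) - lfactorial(y),
      grad = function(y, eta) y - exp(eta),
      winfo = function(y, eta) exp(eta)),
    binomial = list(
      ll = function(y, eta) y * eta - log1p(exp(eta)),
      grad = function(y, eta) y - stats::plogis(eta),
      winfo = function(y, eta) { p <- stats::plogis(eta); p * (1 - p) }),
    abort_input("unknown family: %s", family))
}

# Fixed-effect linear predictor of a prepared fit-free design.
fixed_eta <- function(spec, data, beta) {
  prep <- prepare_design(spec, data)
  X <- cbind(`(Intercept)` = 1, as.matrix(prep$data[, prep$terms, drop = FALSE]))
  list(eta = as.numeric(X %*% beta), data = prep$data)
}

#' Laplace-approximate marginal log-likelihood at fixed parameters
#'
#' Independent implementation of the Laplace objective for a model with a
#' subject random intercept and (optionally) observation-level random
#' effects: per subject, Newton iterations find the joint mode of the latent
#' vector, and the marginal likelihood is approximated by the Gaussian
#' integral at the mode. Exists to validate the fitting machinery against
#' the brute-force quadrature oracle on small instances.
#'
#' @param spec A [model_spec()].
#' @param data The data.
#' @param beta Fixed-effect vector, intercept first, then `spec$fixed` and
#'   interaction terms in spec order.
#' @param subject_sd,olre_sd Random-effect SDs (olre only for poisson).
#' @return Scalar log-likelihood.
#' @export
laplace_loglik <- function(spec, data, beta, subject_sd, olre_sd = 0) {
  fam <- family_loglik(spec$family)
  fe <- fixed_eta(spec, data, beta)
  d <- fe$data
  total <- 0
  for (s in unique(d[[spec$subject]])) {
    idx <- which(d[[spec$subject]] == s)
    y <- d[[spec$outcome]][idx]
    eta0 <- fe$eta[idx]
    ni <- length(idx)
    use_olre <- spec$olre && olre_sd > 0
    q <- 1L + if (use_olre) ni else 0L
    prec <- c(1 / subject_sd^2, if (use_olre) rep(1 / olre_sd^2, ni))
    b <- rep(0, q)
    for (iter in 1:100) {
      eta <- eta0 + b[1] + if (use_olre) b[-1] else 0
      g_eta <- fam$grad(y, eta)
      w <- fam$winfo(y, eta)
      grad <- c(sum(g_eta), if (use_olre) g_eta) - prec * b
      H <- matrix(0, q, q)
      H[1, 1] <- sum(w)
      if (use_olre) {
        H[1, -1] <- w; H[-1, 1] <- w
        diag(H)[-1] <- w
      }
      diag(H) <- diag(H) + prec
      step <- solve(H, grad)
      b <- b + step
      if (max(abs(step)) < 1e-10) break
    }
    eta <- eta0 + b[1] + if (use_olre) b[-1] else 0
    gj <- sum(fam$ll(y, eta)) - 0.5 * sum(prec * b^2) -
      0.5 * sum(log(2 * pi / prec))
    w <- fam$winfo(y, eta)
    H <- matrix(0, q, q)
    H[1, 1] <- sum(w)
    if (use_olre) { H[1, -1] <- w; H[-1, 1] <- w; diag(H)[-1] <- w }
    diag(H) <- diag(H) + prec
    total <- total + gj + 0.5 * q * log(2 * pi) -
      0.5 * as.numeric(determinant(H, logarithm = TRUE)$modulus)
  }
  total
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Brute-force quadrature marginal log-likelihood
#'
#' Exact (to quadrature accuracy) marginal log-likelihood by nested
#' Gauss-Hermite integration over the full latent vector of each subject --
#' dimension `1 + n_i` when observation-level effects are present. Only
#' feasible for tiny instances; serves as the oracle for
#' [laplace_loglik()] and for the fitted models' reported likelihoods.
#'
#' @inheritParams laplace_loglik
#' @param nodes Quadrature nodes per dimension (default 25).
#' @return Scalar log-likelihood.
#' @export
quadrature_loglik <- function(spec, data, beta, subject_sd, olre_sd = 0,
                              nodes = 25) {
  fam <- family_loglik(spec$family)
  fe <- fixed_eta(spec, data, beta)
  d <- fe$data
  gh <- gauss_hermite(nodes)
  total <- 0
  for (s in unique(d[[spec$subject]])) {
    idx <- which(d[[spec$subject]] == s)
    y <- d[[spec$outcome]][idx]
    eta0 <- fe$eta[idx]
    ni <- length(idx)
    use_olre <- spec$olre && olre_sd > 0
    # integrate over u; inner OLRE integrals factor across observations
    lik_u <- vapply(gh$nodes, function(zu) {
      u <- sqrt(2) * subject_sd * zu
      if (!use_olre) {
        exp(sum(fam$ll(y, eta0 + u)))
      } else {
        prod(vapply(seq_len(ni), function(i) {
          sum(gh$weights / sqrt(pi) *
                exp(fam$ll(y[i], eta0[i] + u + sqrt(2) * olre_sd * gh$nodes)))
        }, numeric(1)))
      }
    }, numeric(1))
    total <- total + log(sum(gh$weights / sqrt(pi) * lik_u))
  }
  total
}
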
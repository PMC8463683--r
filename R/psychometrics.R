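# Psychometric curve fitting, adaptive Bayesian calibration and the
# participant-exclusion rule.
#
# 2AFC curves are parameterized folded with zero lapse rate:
#   P(correct | coherence c) = 0.5 + 0.5 * F(slope * (c - inflexion))
# where F is the logistic or standard-normal CDF. Accuracy is 0.75 at the
# inflexion point (the steepest point of the folded curve) and tends to 0.5
# as the curve flattens.

link_cdf <- function(link) switch(link, logit = stats::plogis,
                                  probit = stats::pnorm,
                                  abort_input("unknown link: %s", link))
link_quantile <- function(link) switch(link, logit = stats::qlogis,
                                       probit = stats::qnorm,
                                       abort_input("unknown link: %s", link))

#' Predicted accuracy of a folded 2AFC psychometric curve
#'
#' @param coherence Stimulus coherence(s).
#' @param slope,inflexion Curve parameters.
#' @param link `"logit"` or `"probit"`.
#' @return Accuracy in `[0.5, 1]` for nonnegative slope.
#' @export
psychometric_accuracy <- function(coherence, slope, inflexion, link = "logit") {
  0.5 + 0.5 * link_cdf(link)(slope * (coherence - inflexion))
}

#' Fit a psychometric curve by maximum likelihood
#'
#' Fits the folded 2AFC curve to binary accuracy data under a Bernoulli
#' likelihood, returning slope, inflexion point and the parameter covariance
#' from the observed information. Separation (slope running to its bound or a
#' singular information matrix) is flagged via `diverged`, never returned as
#' a silent number.
#'
#' @param trials Data frame with columns `coherence` and `correct` (0/1).
#' @param link `"logit"` (calibration convention) or `"probit"` (confidence
#'   forced-choice convention).
#' @return An object of class `psychometric_fit`: `slope`, `inflexion`,
#'   `covariance`, `logLik`, `n_trials`, `link`, `diverged`.
#' @export
fit_psychometric <- function(trials, link = "logit") {
  check_columns(trials, c("coherence", "correct"), "psychometric trials")
  if (length(unique(trials$coherence)) < 2L)
    abort_input("need >= 2 distinct coherence levels to fit a psychometric curve")
  coh <- trials$coherence
  y <- trials$correct
  F <- link_cdf(link)
  nll <- function(par) {
    p <- pmin(pmax(0.5 + 0.5 * F(par[1] * (coh - par[2])), 1e-9), 1 - 1e-9)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  slope_hi <- 1e3
  starts <- list(c(5, stats::median(coh)), c(1, mean(coh)), c(20, min(coh)))
  best <- NULL
  for (st in starts) {
    o <- try(stats::optim(st, nll, method = "L-BFGS-B",
                          lower = c(1e-8, -2), upper = c(slope_hi, 2)),
             silent = TRUE)
    if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
      best <- o
  }
  if (is.null(best)) abort_input("psychometric fit failed from all starts")
  diverged <- best$par[1] > 0.99 * slope_hi
  hess <- try(stats::optimHess(best$par, nll), silent = TRUE)
  covariance <- matrix(NA_real_, 2, 2)
  if (!inherits(hess, "try-error")) {
    cv <- try(solve(hess), silent = TRUE)
    if (!inherits(cv, "try-error") && all(is.finite(cv)) &&
        all(diag(cv) >= 0)) {
      covariance <- (cv + t(cv)) / 2
    } else diverged <- TRUE
  } else diverged <- TRUE
  dimnames(covariance) <- list(c("slope", "inflexion"), c("slope", "inflexion"))
  structure(list(slope = best$par[1], inflexion = best$par[2],
                 covariance = covariance, logLik = -best$value,
                 n_trials = nrow(trials), link = link, diverged = diverged),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s link, folded 2AFC)\n", x$link))
  cat(sprintf("  slope = %.3f, inflexion = %.4f, n = %d, logLik = %.2f%s\n",
              x$slope, x$inflexion, x$n_trials, x$logLik,
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Invert a psychometric curve for target accuracies
#'
#' Maps target accuracies through the inverse of the fitted folded link to
#' coherence levels, clipped to `[0, 1]`. Used to place test stimuli so that
#' performance spans roughly 50-100% correct.
#'
#' @param fit A [fit_psychometric()] result (or any list with `slope`,
#'   `inflexion`, `link`).
#' @param targets Accuracy targets in `[0.5, 1)`; default is an even grid
#'   whose mean sits near the ~70%-correct calibration target.
#' @return Numeric vector of coherences.
#' @export
select_test_coherences <- function(fit, targets = seq(0.55, 0.95, by = 0.05)) {
  if (!is.finite(fit$slope) || fit$slope <= 0)
    abort_input("degenerate psychometric slope (%g); cannot invert", fit$slope)
  if (any(targets < 0.5) || any(targets >= 1))
    abort_input("accuracy targets must lie in [0.5, 1)")
  q <- link_quantile(fit$link)((targets - 0.5) / 0.5)
  pmin(pmax(fit$inflexion + q / fit$slope, 0), 1)
}

#' Apply the group-level outlier-exclusion rule
#'
#' A subject is discarded when the calibration slope falls more than two
#' standard errors below the group mean slope, or the inflexion-point
#' coherence more than two standard errors above the group mean inflexion.
#' The two rules apply independently; boundary cases (exactly two SE away)
#' are kept. "SE" defaults to the standard error of the group mean; set
#' `dispersion = "sd"` to use the group standard deviation instead.
#'
#' @param fits Data frame with columns `subject_id`, `slope`, `inflexion`, or
#'   a named list of `psychometric_fit` objects.
#' @param n_se Number of SEs defining the exclusion margin (default 2).
#' @param dispersion `"se"` (standard error of the mean) or `"sd"`.
#' @return List with `kept`, `discarded` (subject ids) and `report` (one row
#'   per discarded subject: rule and margin in SE units).
#' @export
reject_outlier_subjects <- function(fits, n_se = 2, dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      subject_id = names(fits) %||% seq_along(fits),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      inflexion = vapply(fits, `[[`, numeric(1), "inflexion")
    )
  }
  check_columns(fits, c("subject_id", "slope", "inflexion"), "fits")
  n <- nrow(fits)
  if (n < 3L) abort_input("need >= 3 subjects for group outlier statistics")
  margin <- function(x) {
    s <- stats::sd(x)
    if (dispersion == "se") s / sqrt(n) else s
  }
  slope_lo <- mean(fits$slope) - n_se * margin(fits$slope)
  infl_hi <- mean(fits$inflexion) + n_se * margin(fits$inflexion)
  bad_slope <- fits$slope < slope_lo        # strict: boundary kept
  bad_infl <- fits$inflexion > infl_hi
  report <- rbind(
    if (any(bad_slope)) data.frame(subject_id = fits$subject_id[bad_slope],
                                   rule = "slope_below",
                                   margin = (mean(fits$slope) - fits$slope[bad_slope]) /
                                     margin(fits$slope)),
    if (any(bad_infl)) data.frame(subject_id = fits$subject_id[bad_infl],
                                  rule = "inflexion_above",
                                  margin = (fits$inflexion[bad_infl] - mean(fits$inflexion)) /
                                    margin(fits$inflexion))
  )
  discarded <- unique(fits$subject_id[bad_slope | bad_infl])
  list(kept = setdiff(fits$subject_id, discarded),
       discarded = discarded,
       report = report %||% data.frame(subject_id = character(0),
                                       rule = character(0), margin = numeric(0)))
}
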
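# Adaptive Bayesian calibration of the psychometric curve.
#
# The design-optimization scheme maintains a discrete grid posterior over
# (slope, inflexion) and, on each trial, presents the candidate coherence
# that maximizes the expected information gain -- the mutual information
# between the upcoming binary response and the parameters under the current
# posterior. This grid-posterior criterion stands in for variational design
# optimization: same objective (maximally improving the model evidence),
# exactly computable on the grid.

#' Initialize a calibration state
#'
#' @param slope_grid,inflexion_grid Parameter grid (defaults cover slopes
#'   0.5-60 log-spaced and inflexion points 0-0.5).
#' @param candidates Candidate coherences presented during calibration.
#' @param link Psychometric link, `"logit"` by default.
#' @param prior Optional prior weight matrix (`length(slope_grid)` x
#'   `length(inflexion_grid)`); uniform when omitted.
#' @return A `calibration_state` with normalized posterior weights, empty
#'   history, and the precomputed accuracy table.
#' @export
calibration_state <- function(slope_grid = exp(seq(log(0.5), log(60), length.out = 41)),
                              inflexion_grid = seq(0, 0.5, length.out = 41),
                              candidates = seq(0.02, 0.98, by = 0.04),
                              link = "logit",
                              prior = NULL) {
  if (!length(candidates)) abort_input("candidate coherence set must be nonempty")
  if (any(candidates <= 0) || any(candidates >= 1))
    abort_input("candidate coherences must lie in (0, 1)")
  grid <- expand.grid(slope = slope_grid, inflexion = inflexion_grid)
  w <- if (is.null(prior)) rep(1, nrow(grid)) else as.numeric(prior)
  w <- w / sum(w)
  # accuracy of every grid point at every candidate, computed once
  acc <- outer(seq_len(nrow(grid)), seq_along(candidates),
               function(i, j) psychometric_accuracy(candidates[j],
                                                    grid$slope[i],
                                                    grid$inflexion[i], link))
  structure(list(grid = grid, weights = w, candidates = candidates,
                 accuracy = acc, link = link,
                 history = data.frame(coherence = numeric(0),
                                      correct = integer(0))),
            class = "calibration_state")
}

#' Expected information gain of each candidate coherence
#'
#' Mutual information (nats) between the next binary response and the grid
#' parameters under the current posterior: `H(E_w[p]) - E_w[H(p)]`.
#'
#' @param state A [calibration_state()].
#' @return Numeric vector over candidates.
#' @export
calibration_info_gain <- function(state) {
  pbar <- as.numeric(crossprod(state$weights, state$accuracy))
  hbar <- as.numeric(crossprod(state$weights, entropy_binary(state$accuracy)))
  entropy_binary(pbar) - hbar
}

#' One Bayesian update of the calibration posterior
#'
#' @param state A [calibration_state()].
#' @param coherence Presented coherence (must be a candidate).
#' @param correct Observed accuracy (0/1).
#' @return Updated state.
#' @export
calibration_update <- function(state, coherence, correct) {
  j <- match(coherence, state$candidates)
  if (is.na(j)) abort_input("coherence %g is not in the candidate set", coherence)
  p <- state$accuracy[, j]
  lik <- if (correct) p else 1 - p
  w <- state$weights * lik
  state$weights <- w / sum(w)
  state$history <- rbind(state$history,
                         data.frame(coherence = coherence,
                                    correct = as.integer(correct)))
  state
}

#' Run the adaptive calibration against an observer
#'
#' Each trial presents the candidate coherence with the largest expected
#' information gain, queries the observer, and updates the grid posterior.
#' The final fit reports posterior means and the posterior covariance of
#' (slope, inflexion).
#'
#' @param observer Either a [subject_profile()] (simulated with
#'   [simulate_observer_trials()]) or a function `function(coherence)`
#'   returning 0/1 accuracy.
#' @param n_trials Number of calibration trials (the protocol uses 120).
#' @param state Optional starting [calibration_state()].
#' @param seed Optional seed.
#' @return List with the final `state` and `fit` (class `psychometric_fit`
#'   with posterior-mean parameters and posterior covariance).
#' @export
adaptive_calibration <- function(observer, n_trials = 120,
                                 state = calibration_state(), seed = NULL) {
  check_number(n_trials, "n_trials", min = 1)
  respond <- if (is.function(observer)) observer
  else if (inherits(observer, "subject_profile"))
    function(coh) simulate_observer_trials(observer, coh, "calibration")$correct
  else abort_input("observer must be a subject_profile or a response function")
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      gain <- calibration_info_gain(state)
      j <- which.max(gain)            # deterministic tie-break: first maximum
      coh <- state$candidates[j]
      state <- calibration_update(state, coh, respond(coh))
    }
    state
  }) -> state
  fit <- calibration_posterior_fit(state)
  list(state = state, fit = fit)
}

#' Posterior summary of a calibration run
#'
#' @param state A [calibration_state()].
#' @return A `psychometric_fit` with posterior-mean slope/inflexion and the
#'   posterior covariance matrix.
#' @export
calibration_posterior_fit <- function(state) {
  w <- state$weights
  m <- c(slope = sum(w * state$grid$slope),
         inflexion = sum(w * state$grid$inflexion))
  d <- cbind(state$grid$slope - m[1], state$grid$inflexion - m[2])
  covariance <- crossprod(d * sqrt(w))
  dimnames(covariance) <- list(c("slope", "inflexion"), c("slope", "inflexion"))
  structure(list(slope = unname(m[1]), inflexion = unname(m[2]),
                 covariance = covariance,
                 logLik = NA_real_, n_trials = nrow(state$history),
                 link = state$link, diverged = FALSE),
            class = "psychometric_fit")
}

#' Posterior entropy of the calibration grid (nats)
#' @param state A [calibration_state()].
#' @return Scalar entropy of the posterior weights.
#' @export
calibration_entropy <- function(state) {
  w <- state$weights[state$weights > 0]
  -sum(w * log(w))
}
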
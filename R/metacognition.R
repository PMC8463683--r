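# Explicit and implicit metacognitive sensitivity.
#
# Explicit: meta-d' under the equal-variance Gaussian type-2 SDT model --
# the sensitivity a metacognitively ideal observer would need at the type-1
# level to produce the observed confidence-rating distributions, holding the
# type-1 criterion at its proportional location. M-ratio = meta-d'/d'.
# Implicit: the confidence modulation index (CMI), the normalized difference
# between psychometric slopes of chosen vs discarded stimuli in a confidence
# forced-choice task.

#' Cross-tabulate explicit-task trials into a rating table
#'
#' @param trials Data frame with `direction` (+/-1), `response` (+/-1) and
#'   `confidence` (integers `1..n_ratings`).
#' @param n_ratings Number of confidence levels (default 6).
#' @return A `2 x 2 x n_ratings` integer array indexed by
#'   (stimulus, response, rating); class `rating_table`.
#' @export
build_rating_table <- function(trials, n_ratings = 6L) {
  check_columns(trials, c("direction", "response", "confidence"), "trials")
  bad <- which(!trials$confidence %in% seq_len(n_ratings))
  if (length(bad))
    abort_input("missing/invalid confidence in rows: %s",
                paste(utils::head(bad, 10), collapse = ", "))
  tab <- table(
    stimulus = factor(trials$direction, levels = c(-1, 1)),
    response = factor(trials$response, levels = c(-1, 1)),
    rating = factor(trials$confidence, levels = seq_len(n_ratings))
  )
  structure(array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab)),
            class = "rating_table")
}

#' Analytic rating-cell probabilities of the Gaussian observer
#'
#' Closed-form cell probabilities P(stimulus, response, rating) for an
#' equal-variance observer with evidence `N(direction * mu, 1)`, confidence
#' evidence `|evidence| + N(0, sigma_meta)` cut at `thresholds`. Used as the
#' independent oracle for the simulated rating tables.
#'
#' @param mu Mean evidence (d-prime / 2 per stimulus class is `mu` here since
#'   the decision criterion sits at 0; d' = 2 * mu... for this observer
#'   d' = 2*qnorm(pnorm(mu)) = 2*mu).
#' @param sigma_meta Meta-noise SD.
#' @param thresholds Ascending confidence cutpoints.
#' @return A `2 x 2 x K` probability array (stimulus, response, rating).
#' @export
sdt_rating_probs <- function(mu, sigma_meta, thresholds) {
  K <- length(thresholds) + 1L
  cuts <- c(-Inf, thresholds, Inf)
  # P(response = r, conf evidence in bin | stimulus s), evidence x ~ N(s*mu,1)
  # conf = |x| + noise. Integrate numerically over x on each response side.
  probs <- array(0, dim = c(2, 2, K),
                 dimnames = list(stimulus = c("-1", "1"),
                                 response = c("-1", "1"),
                                 rating = seq_len(K)))
  for (si in 1:2) {
    s <- c(-1, 1)[si]
    for (ri in 1:2) {
      r <- c(-1, 1)[ri]
      dens <- function(x) stats::dnorm(x, mean = s * mu)
      for (k in seq_len(K)) {
        f <- function(x) {
          ax <- abs(x)
          pk <- if (sigma_meta > 0)
            stats::pnorm(cuts[k + 1], ax, sigma_meta) -
              stats::pnorm(cuts[k], ax, sigma_meta)
          else as.numeric(ax >= cuts[k] & ax < cuts[k + 1])
          dens(x) * pk
        }
        probs[si, ri, k] <- if (r > 0)
          stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
        else stats::integrate(f, -Inf, 0, rel.tol = 1e-9)$value
      }
    }
  }
  probs
}

# Conditional rating probabilities P(rating | stimulus, response) of the
# meta-level Gaussian observer with sensitivity meta_d, type-1 criterion at
# cprime, and type-2 criteria t2_low (descending from cprime) / t2_high
# (ascending from cprime).
meta_rating_probs <- function(meta_d, cprime, t2_low, t2_high, K) {
  mus <- c(-meta_d / 2, meta_d / 2)
  out <- array(0, dim = c(2, 2, K))
  lo <- c(cprime, t2_low, -Inf)   # boundaries going down; rating r in (lo[r+1], lo[r])
  hi <- c(cprime, t2_high, Inf)   # boundaries going up
  for (si in 1:2) {
    mu <- mus[si]
    p_lo <- stats::pnorm(lo, mean = mu)
    p_hi <- stats::pnorm(hi, mean = mu)
    denom_low <- stats::pnorm(cprime, mean = mu)
    denom_high <- 1 - denom_low
    out[si, 1, ] <- (p_lo[seq_len(K)] - p_lo[seq_len(K) + 1L]) / denom_low
    out[si, 2, ] <- (p_hi[seq_len(K) + 1L] - p_hi[seq_len(K)]) / denom_high
  }
  out
}

#' Fit meta-d' to a rating table
#'
#' Type-1 d' and criterion come from the table margins; meta-d' is fit by
#' maximum likelihood over the confidence-rating probabilities of an
#' equal-variance Gaussian observer whose type-1 criterion is held at the
#' proportional location `c' = c * meta_d / d'`. A single meta-d' is fit
#' across both responses. Cells are padded by `padding` (default `1/(2K)`)
#' inside the fit only.
#'
#' @param table A [build_rating_table()] result (2 x 2 x K counts).
#' @param padding Per-cell count added before fitting; default `1/(2*K)`.
#' @param n_starts Number of optimizer starts (multi-start BFGS).
#' @return A `metacog_estimates` list: `d_prime`, `criterion`, `meta_d`,
#'   `m_ratio`, `logLik`, `converged`, `defined`.
#' @export
fit_meta_d <- function(table, padding = NULL, n_starts = 3L) {
  K <- dim(table)[3]
  if (is.null(padding)) padding <- 1 / (2 * K)
  n <- array(as.numeric(table), dim = dim(table)) + padding
  # type-1 from padded margins
  n1 <- apply(n, c(1, 2), sum)
  hr <- n1[2, 2] / sum(n1[2, ])   # P(resp + | stim +)
  far <- n1[1, 2] / sum(n1[1, ])  # P(resp + | stim -)
  d_prime <- stats::qnorm(hr) - stats::qnorm(far)
  criterion <- -0.5 * (stats::qnorm(hr) + stats::qnorm(far))
  if (!is.finite(d_prime) || d_prime <= 0) {
    return(structure(list(d_prime = d_prime, criterion = criterion,
                          meta_d = NA_real_, m_ratio = NA_real_,
                          logLik = NA_real_, converged = FALSE,
                          defined = FALSE), class = "metacog_estimates"))
  }
  c_rel <- criterion / d_prime
  nll <- function(par) {
    meta_d <- par[1]
    gaps_low <- exp(par[2:K])
    gaps_high <- exp(par[(K + 1):(2 * K - 1)])
    cprime <- c_rel * meta_d
    t2_low <- cprime - cumsum(gaps_low)
    t2_high <- cprime + cumsum(gaps_high)
    pr <- meta_rating_probs(meta_d, cprime, t2_low, t2_high, K)
    pr <- pmin(pmax(pr, 1e-12), 1)
    -sum(n * log(pr))
  }
  start_meta <- c(d_prime, 0.5 * d_prime, 1.5 * d_prime)[seq_len(n_starts)]
  best <- NULL
  for (sm in start_meta) {
    st <- c(sm, rep(log(0.4), 2 * (K - 1)))
    o <- try(stats::optim(st, nll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
    if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
      best <- o
  }
  if (is.null(best)) {
    return(structure(list(d_prime = d_prime, criterion = criterion,
                          meta_d = NA_real_, m_ratio = NA_real_,
                          logLik = NA_real_, converged = FALSE,
                          defined = FALSE), class = "metacog_estimates"))
  }
  meta_d <- best$par[1]
  structure(list(d_prime = d_prime, criterion = criterion, meta_d = meta_d,
                 m_ratio = meta_d / d_prime, logLik = -best$value,
                 converged = best$convergence == 0, defined = TRUE),
            class = "metacog_estimates")
}

#' @export
print.metacog_estimates <- function(x, ...) {
  if (!is.null(x$cmi)) {
    cat(sprintf("CMI = %.3f (chosen slope %.3f, discarded slope %.3f)%s\n",
                x$cmi, x$fit_chosen$slope, x$fit_discarded$slope,
                if (!x$defined) " [UNDEFINED]" else ""))
  } else {
    cat(sprintf("d' = %.3f, criterion = %.3f, meta-d' = %.3f, M-ratio = %.3f%s\n",
                x$d_prime, x$criterion, x$meta_d, x$m_ratio,
                if (!x$defined) " [UNDEFINED]" else ""))
  }
  invisible(x)
}

#' Type-1 and type-2 ROC curves from a rating table
#'
#' Type-1: cumulative hit/false-alarm rates over the combined
#' response-confidence ordinal scale. Type-2: hit rate = P(confidence >= cut |
#' correct), false-alarm rate = P(confidence >= cut | incorrect), pooled over
#' responses. Both curves run from (0,0) to (1,1) and are monotone.
#'
#' @param table A [build_rating_table()] result.
#' @return List of two data frames `type1` and `type2` with columns `far`,
#'   `hr`, plus the trapezoidal `auc` of each as attributes-free named
#'   scalars `auc1`, `auc2`.
#' @export
type2_roc <- function(table) {
  K <- dim(table)[3]
  n <- array(as.numeric(table), dim = dim(table))
  # combined 2K-point ordinal: resp=-1 rating K..1, then resp=+1 rating 1..K
  scale_counts <- function(si) c(rev(n[si, 1, ]), n[si, 2, ])
  s_pos <- scale_counts(2); s_neg <- scale_counts(1)
  cum_tail <- function(x) rev(cumsum(rev(x))) / max(sum(x), 1)
  hr1 <- c(cum_tail(s_pos), 0); far1 <- c(cum_tail(s_neg), 0)
  type1 <- data.frame(far = rev(far1), hr = rev(hr1))
  # type-2 pooled: correct = diagonal cells, incorrect = off-diagonal
  corr <- n[1, 1, ] + n[2, 2, ]
  incorr <- n[1, 2, ] + n[2, 1, ]
  h2 <- c(cum_tail(corr), 0); f2 <- c(cum_tail(incorr), 0)
  type2 <- data.frame(far = rev(f2), hr = rev(h2))
  auc <- function(d) sum(diff(d$far) * (utils::head(d$hr, -1) + utils::tail(d$hr, -1)) / 2)
  list(type1 = type1, type2 = type2, auc1 = auc(type1), auc2 = auc(type2))
}

#' Confidence modulation index from forced-choice pairs
#'
#' Fits folded psychometric curves (probit link by convention) to the chosen
#' and the discarded trials separately and returns
#' `cmi = (slope_chosen - slope_discarded) / mean(slopes)`. Positive CMI
#' means the observer preferentially trusts trials on which it is indeed more
#' accurate -- implicit metacognitive sensitivity.
#'
#' @param pairs Trial records with `pair_id`, `chosen`, `coherence`,
#'   `correct`; each pair must contain exactly two trials, exactly one
#'   chosen.
#' @param link Link function, `"probit"` by default.
#' @return `metacog_estimates` with `cmi`, the two `psychometric_fit`s and a
#'   `defined` flag (FALSE when the average slope is non-positive or a fit
#'   diverged).
#' @export
compute_cmi <- function(pairs, link = "probit") {
  check_columns(pairs, c("pair_id", "chosen", "coherence", "correct"), "pairs")
  per_pair <- table(pairs$pair_id)
  if (any(per_pair != 2L))
    abort_input("each pair_id must group exactly two trials")
  chosen_per <- tapply(pairs$chosen, pairs$pair_id, sum)
  if (any(chosen_per != 1L))
    abort_input("each pair must have exactly one chosen trial")
  fit_c <- fit_psychometric(pairs[pairs$chosen, ], link = link)
  fit_d <- fit_psychometric(pairs[!pairs$chosen, ], link = link)
  avg <- (fit_c$slope + fit_d$slope) / 2
  defined <- avg > 0 && !fit_c$diverged && !fit_d$diverged
  cmi <- if (avg > 0) (fit_c$slope - fit_d$slope) / avg else NA_real_
  structure(list(cmi = cmi, fit_chosen = fit_c, fit_discarded = fit_d,
                 defined = defined), class = "metacog_estimates")
}

#' Serialize a rating table to CSV
#'
#' One row per response class, `K` confidence columns per stimulus class, for
#' interoperability with existing meta-d' toolboxes.
#' @param table A [build_rating_table()] result.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_rating_table <- function(table, path) {
  K <- dim(table)[3]
  df <- data.frame(response = c(-1, 1))
  for (si in 1:2) for (k in seq_len(K))
    df[[sprintf("stim%s_conf%d", c("neg", "pos")[si], k)]] <- table[si, , k]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
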
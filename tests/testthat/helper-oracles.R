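# Independent oracles used across the suite. These reimplement the checked
# quantities by brute force (grid search, direct simulation, closed forms)
# without calling the package's own fitting paths.

# Grid-search MLE for the folded 2AFC psychometric curve.
grid_psychometric_mle <- function(coherence, correct, link = "logit",
                                  slopes = seq(0.5, 40, by = 0.25),
                                  inflexions = seq(0, 0.5, by = 0.005)) {
  F <- if (link == "logit") stats::plogis else stats::pnorm
  best <- list(nll = Inf)
  for (s in slopes) {
    # vectorize over inflexions for speed
    nlls <- vapply(inflexions, function(m) {
      p <- pmin(pmax(0.5 + 0.5 * F(s * (coherence - m)), 1e-9), 1 - 1e-9)
      -sum(correct * log(p) + (1 - correct) * log(1 - p))
    }, numeric(1))
    j <- which.min(nlls)
    if (nlls[j] < best$nll)
      best <- list(nll = nlls[j], slope = s, inflexion = inflexions[j])
  }
  best
}

# Brute-force meta-d' fit for a 2x2x2 (binary-confidence) rating table by
# dense grid search. The likelihood factorizes over response sides, so the
# grid is meta_d x (lower gap) + meta_d x (upper gap).
meta_d_grid_fit <- function(tab, padding = 1 / 4,
                            meta_grid = seq(0.05, 3.5, by = 0.01),
                            gap_grid = seq(0.02, 3, by = 0.01)) {
  n <- array(as.numeric(tab), dim = dim(tab)) + padding
  n1 <- apply(n, c(1, 2), sum)
  hr <- n1[2, 2] / sum(n1[2, ]); far <- n1[1, 2] / sum(n1[1, ])
  d_prime <- qnorm(hr) - qnorm(far)
  c_rel <- (-0.5 * (qnorm(hr) + qnorm(far))) / d_prime
  best <- list(nll = Inf)
  for (md in meta_grid) {
    cp <- c_rel * md
    mus <- c(-md / 2, md / 2)
    nll_low <- vapply(gap_grid, function(g) {
      l <- cp - g
      out <- 0
      for (si in 1:2) {
        denom <- pnorm(cp, mus[si])
        p2 <- pnorm(l, mus[si]) / denom
        p1 <- 1 - p2
        out <- out - n[si, 1, 1] * log(max(p1, 1e-12)) -
          n[si, 1, 2] * log(max(p2, 1e-12))
      }
      out
    }, numeric(1))
    nll_high <- vapply(gap_grid, function(g) {
      h <- cp + g
      out <- 0
      for (si in 1:2) {
        denom <- 1 - pnorm(cp, mus[si])
        p2 <- (1 - pnorm(h, mus[si])) / denom
        p1 <- 1 - p2
        out <- out - n[si, 2, 1] * log(max(p1, 1e-12)) -
          n[si, 2, 2] * log(max(p2, 1e-12))
      }
      out
    }, numeric(1))
    tot <- min(nll_low) + min(nll_high)
    if (tot < best$nll) best <- list(nll = tot, meta_d = md)
  }
  best
}

# Tiny fixture datasets on which the Laplace approximation is accurate
# enough (well-informed latents) to be compared with exact quadrature.
laplace_fixtures <- function() {
  set.seed(4242)
  list(
    poisson_olre = list(
      spec = metacheck::model_spec("y", fixed = "x", family = "poisson",
                                   subject = "sid", olre = TRUE,
                                   standardize = FALSE),
      data = data.frame(sid = rep(1:2, each = 3), x = rnorm(6, 0, 0.3),
                        y = rpois(6, 20)),
      beta = c(log(20), 0.2), subject_sd = 0.2, olre_sd = 0.15),
    poisson_subject = list(
      spec = metacheck::model_spec("y", fixed = "x", family = "poisson",
                                   subject = "sid", olre = FALSE,
                                   standardize = FALSE),
      data = data.frame(sid = rep(1:3, each = 4), x = rnorm(12, 0, 0.5),
                        y = rpois(12, 8)),
      beta = c(log(8), 0.1), subject_sd = 0.3, olre_sd = 0),
    binomial_subject = list(
      spec = metacheck::model_spec("y", fixed = "x", family = "binomial",
                                   subject = "sid", standardize = FALSE),
      data = data.frame(sid = rep(1:3, each = 100), x = rnorm(300),
                        y = rbinom(300, 1, 0.5)),
      beta = c(0.1, -0.3), subject_sd = 0.5, olre_sd = 0)
  )
}

# Direct (package-free) simulation of the confidence forced-choice task for
# one observer; returns chosen/discarded psychometric slopes via the grid
# MLE above.
simulate_cfc_oracle <- function(k, sigma_meta, coh_a, coh_b, seed) {
  set.seed(seed)
  n <- length(coh_a)
  dir_a <- sample(c(-1, 1), n, TRUE); dir_b <- sample(c(-1, 1), n, TRUE)
  ev_a <- rnorm(n, dir_a * k * coh_a); ev_b <- rnorm(n, dir_b * k * coh_b)
  conf_a <- abs(ev_a) + rnorm(n, 0, sigma_meta)
  conf_b <- abs(ev_b) + rnorm(n, 0, sigma_meta)
  pick_a <- conf_a > conf_b
  corr_a <- as.numeric(sign(ev_a) == dir_a); corr_b <- as.numeric(sign(ev_b) == dir_b)
  ch_coh <- ifelse(pick_a, coh_a, coh_b); ch_cor <- ifelse(pick_a, corr_a, corr_b)
  di_coh <- ifelse(pick_a, coh_b, coh_a); di_cor <- ifelse(pick_a, corr_b, corr_a)
  slopes <- c(
    chosen = grid_psychometric_mle(ch_coh, ch_cor, link = "probit")$slope,
    discarded = grid_psychometric_mle(di_coh, di_cor, link = "probit")$slope
  )
  (slopes[["chosen"]] - slopes[["discarded"]]) / mean(slopes)
}
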
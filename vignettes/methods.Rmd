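---
title: "Models and methods behind metacheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metacheck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

metacheck studies a simple question with a lot of statistical machinery
behind it: when people are allowed to *check* — to replay a perceptual
stimulus before committing to a decision — is that checking driven by their
uncertainty, and does it depend on how well they can monitor their own
perception (their metacognition)? The package provides the full simulation
and estimation tool chain for this paradigm: a generative model of the
observers, psychometric calibration, two estimators of metacognitive
sensitivity, and the mixed-effects regression models that tie checking to
difficulty and traits.

## The observer model

The mechanistic cohort mode simulates equal-variance signal-detection
observers performing two-alternative (left/right) motion judgments. On a
trial with coherence $c \in [0,1]$ and direction $d = \pm 1$, sensory
evidence is

$$x \sim \mathcal{N}(d \cdot k \cdot c,\ 1),$$

and the response is $\operatorname{sign}(x)$, so accuracy is $\Phi(k c)$.
The sensitivity $k$ (evidence units per unit coherence, default mean 5.2
across subjects) sets where the ~70%-correct calibration point falls
(around coherence 0.1, typical for random-dot-motion work). Confidence is a
second-order readout: $\,|x| + \varepsilon$, $\varepsilon \sim
\mathcal{N}(0, \sigma_{\mathrm{meta}}^2)$, cut at five fixed thresholds into
a 1–6 rating. $\sigma_{\mathrm{meta}} = 0$ produces a metacognitively ideal
observer (M-ratio $\approx$ 1); the default 0.5 produces the sub-unit
M-ratios typical of human data. This generator is the package's own choice:
the experimental paradigm specifies tasks, not a generative mechanism.

What a green test on this cohort does establish: the estimators recover the
quantities this observer family defines (M-ratio decreasing in meta-noise,
positive CMI for an evidence-comparing chooser, chance accuracy at zero
coherence). What it does not establish: robustness to lapses, response
biases that drift over time, confidence criteria that shift between tasks,
or serial dependencies — none of which are generated.

## Psychometric curves and calibration

2AFC accuracy curves are parameterized folded with zero lapse rate,

$$P(\text{correct} \mid c) = \tfrac12 + \tfrac12 F\!\big(s (c - m)\big),$$

with $F$ logistic (calibration convention) or probit (confidence
forced-choice convention), slope $s$ and inflexion point $m$ (accuracy 0.75
at $m$). Lapse/guess-rate estimation is deliberately omitted; separation
(all-correct data) is flagged via a `diverged` indicator instead of being
returned silently.

The adaptive calibration replaces the cited variational design-optimization
scheme with a discrete grid posterior over $(s, m)$ (41 × 41, slopes
log-spaced 0.5–60, inflexions 0–0.5) and selects, each trial, the candidate
coherence maximizing the mutual information between the upcoming binary
response and the parameters. The objective is the same (maximally improving
model evidence); the grid form is exactly computable and therefore exactly
testable. With 120 trials — the protocol's calibration length — the
posterior-mean slope lands within ~15% of the truth for on-model observers.

The exclusion rule discards a subject whose calibration slope is more than
2 standard errors below the group mean slope, or whose inflexion coherence
is more than 2 SE above the group mean; boundary cases are kept (strict
inequalities). Whether "SE" meant standard error of the mean or group SD is
ambiguous in the source description; the package defaults to SE of the mean
and exposes `dispersion = "sd"`. Under the SE reading the rule is strict:
on heterogeneous simulated cohorts it can discard a large fraction
(~30–40%) of subjects, which is worth knowing before using it at small $n$.

## Explicit metacognition: meta-d′ and M-ratio

Ratings are cross-tabulated into a 2 × 2 × 6 (stimulus × response ×
confidence) table. Type-1 $d'$ and criterion $c$ come from the padded table
margins. Meta-d′ asks: what type-1 sensitivity would an SDT-ideal observer
need so that its confidence ratings reproduce the observed type-2 (rating)
distributions, holding its criterion at the proportional location
$c' = c \cdot d'_{\mathrm{meta}} / d'$? It is fit by maximum likelihood over
the rating probabilities conditional on stimulus and response, with a
single meta-d′ across both responses (one M-ratio per subject is reported,
so response-specific fitting is not implemented). Numerical choices: every
cell is padded by $1/(2K)$ (K = number of ratings) inside the fit only;
type-2 criteria are parameterized as ordered log-gaps around $c'$;
multi-start BFGS with relative tolerance 1e-10; the test suite requires the
optimizer to match a dense grid search on binary-confidence tables.

## Implicit metacognition: the confidence modulation index

In the confidence forced-choice task the observer judges two stimuli and
then picks the one it trusts more. Folded probit psychometric curves are
fit separately to chosen and discarded trials and

$$\mathrm{CMI} = \frac{s_{\text{chosen}} - s_{\text{discarded}}}
{(s_{\text{chosen}} + s_{\text{discarded}})/2}.$$

The sign convention is chosen − discarded (positive = good implicit
metacognition), matching the task's figure-level definition; the index is
exactly antisymmetric under swapping the labels, which the suite asserts to
1e-10. CMI is flagged undefined when either fit diverges or the average
slope is non-positive.

## The checking and accuracy models

The checking-count model is a Poisson GLMM:

$$\log \mathbb{E}[\text{checks}] = \beta_0 + \beta_z z + \textstyle\sum_k
\beta_k t_k + \sum_k \gamma_k\, t_k z + u_{\text{subj}} + e_{\text{obs}},$$

with standardized difficulty $z$ (negative z-scored coherence, so harder =
larger, making the difficulty slope positive as conventionally reported),
trait covariates $t_k$ (M-ratio, CMI, obsessive–compulsive symptom score,
cognitive-mistrust score), a subject random intercept
$u \sim \mathcal{N}(0, \tau^2)$ and a lognormal observation-level random
effect $e \sim \mathcal{N}(0, \sigma^2_{\mathrm{olre}})$ absorbing
overdispersion (Gaussian on the log scale, matching the mixed-model
formulation — not gamma). The accuracy model is a logistic GLMM in
difficulty, standardized checks, checks × difficulty, traits and
trait × checks, with a subject intercept.

Generator defaults are the published interaction/slope estimates
($\beta_z = 0.90$; checks $=-0.26$; checks × difficulty $= 0.20$;
M-ratio × difficulty $= 0.08$; CMI × difficulty $=-0.05$;
Padua × difficulty $= 0.10$; mistrust × difficulty $=-0.09$). Coefficients
the source never prints are package choices made once: $\beta_0$ set so the
marginal rate is 0.6 checks/trial at average difficulty (the source never
reports the mean count, so it cannot be anchored); trait main effects 0;
accuracy intercept $\operatorname{logit}(0.70)$ with difficulty slope
−0.90 mirroring the perceptual effect; $\tau = \sigma_{\mathrm{olre}} =
0.5$ and a 0.8 subject SD for accuracy — mid-range values for behavioral
count/accuracy data. Trait covariates are generated already standardized;
the fitting pipeline re-standardizes empirically, and the small attenuation
this causes is absorbed by the stochastic test tolerances.

Fitting uses Laplace-approximate maximum likelihood via lme4 — the nested
conditional-independence structure makes Laplace $O(n)$ per iteration,
whereas adaptive quadrature is infeasible with per-observation latents. Two
independent implementations guard this: `laplace_loglik()` re-derives the
Laplace objective from scratch (per-subject Newton on the latent vector),
and `quadrature_loglik()` integrates the latents exactly by nested
Gauss-Hermite quadrature. On fixture data with well-informed latents
(Poisson means ≈ 8–20, or ≥ 100 Bernoulli observations per subject) all
three agree to 1e-4 relative; at sparse counts (mean ≈ 2, the realistic
checking regime) the Laplace error grows to ≈ 1e-3 relative — a known
property of the approximation, relevant when comparing log-likelihoods
across software.

Inference machinery: Wald $z = b/\mathrm{SE}$ with two-sided normal
p-values (unadjusted — no multiple-testing correction is applied); VIF per
predictor with the conventional < 3 reading; percentile parametric
bootstrap CIs (default 1000 replicates; a count the source does not state);
and the equality-constrained likelihood-ratio test, implemented literally:
the two design columns are replaced by their sum, which forces the two
coefficients to be equal, giving a 1-df chi-square. Interactions are
materialized as explicit product columns of standardized mains precisely so
this restriction is a column operation.

The one-sample Wilcoxon signed-rank test is implemented with an exact null
distribution built by subset-sum dynamic programming over ranks (two-tailed
p doubles the smaller tail, capped at 1), and a normal approximation with
0.5 continuity correction toward the null mean. Exact mode refuses ties and
zeros rather than silently mid-ranking. The pipeline's group tests use the
normal-cc method because estimated measures can tie in absolute value.

## Degenerate inputs and tie-breaks

Zero-variance predictors fail standardization with the column named;
rank-deficient designs fail `vif()` with the dependent columns named, while
`fit_glmm()` records the diagnostic as NA and proceeds (so an exactly
aliased restricted model yields LRT statistic 0, p = 1); calibration
tie-breaks take the first maximal-information candidate; `n_checks` missing
makes accuracy simulation fail rather than impute; a non-positive $d'$
marks all meta-d′ outputs undefined rather than dividing by it.

## Known limitations

No lapse-rate or staircase psychometrics; no response-specific meta-d′ or
hierarchical/Bayesian variants; no random slopes or crossed random effects;
no reaction-time or learning dynamics; the correlation Bayes factor
reported alongside the original null correlation is not implemented (its
method is unspecified). The deposited-data importer is a documented stub:
the OSF deposit's file schema is not machine-readable from the source, so
`osf_adapter_schema()` only states the tables an adapter must produce.
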
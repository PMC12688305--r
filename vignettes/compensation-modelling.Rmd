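---
title: "Modelling guilt- and shame-driven compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling guilt- and shame-driven compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralcomp)
```

## The task and its measurements

`moralcomp` models behaviour in an interpersonal compensation game. A
participant ("decider") and three co-players make perceptual estimates; when
any of them errs, a fifth player (the receiver) suffers an electric shock
whose intensity is the *harm level* `H` (1–4). The number of deciders who
erred, the *wrongdoers* `W` (1–4), manipulates how much of the blame falls
on the participant: the *responsibility level* is `R = 5 - W`. On each trial
the participant holds 10 tokens (0.5 yuan each) and may transfer any integer
amount `D` from 0 to 10 to the receiver. The experimental ("self-error")
trials form a 4 × 4 within-subject factorial repeated 4 times — 64 trials —
interleaved with 48 filler trials (correct-estimate outcomes) across 4
sessions of 16 + 12. After the game, participants rate the guilt and the
shame they felt for each of the 16 harm × responsibility cells on 0–10
Likert scales, rate pain per harm level and perceived responsibility per
responsibility level (1–9), and supply trait questionnaire scores.

`design_spec()` carries these constants and `build_schedule()` instantiates
the per-participant trial order. Fillers never enter any analysis, so they
are scheduled as bare placeholders with empty harm/wrongdoer fields.
"Pseudo-random order" is implemented as a uniform within-session shuffle
with the constraint that the same cell never occupies two consecutive
experimental trials; after 1000 failed shuffles the constraint is dropped
(at the default design it essentially never binds).

## The utility family

The core question is how `H` and `W` are integrated into a felt obligation.
Two families formalise the candidates:

* **Responsibility diffusion** (models 1.1–1.4): obligation tracks the
  average harm per wrongdoer, `H / W`.
* **Harm amplification** (models 2.1–2.4): responsibility multiplies harm,
  `H * R`.

Within each family, the full model

$$U(D) = \theta\,(10 - D) - (1 - \theta)\,\lvert \kappa A + \eta - D \rvert,$$

with `A` the family's integration term, crosses two optional components:
self-interest (the retained tokens, weighted by greed $\theta \in [0,1]$)
and a compensatory baseline $\eta$ (tokens given regardless of harm). The
x.3 variants drop self-interest, the x.2 variants drop the baseline, x.4
drops both. $\kappa$ is the compensatory sensitivity — tokens per unit of
attributed harm — and the absolute value encodes aversion to both under-
and over-compensating the amount $\kappa A + \eta$ the decider believes is
deserved. Ideal points may be non-integer; no rounding is applied inside
the utility, the distance term handles fractional ideal points naturally.

Utilities map to choice probabilities with a softmax,
$P(D) \propto e^{\lambda U(D)}$, over the 11 options. The inverse
temperature $\lambda \ge 0$ spans random choice (0) to deterministic
utility maximisation (large). Internally `W` is stored and `R` derived on
demand, keeping the invariant `W + R = 5` in one place.

## Fitting and model comparison

`fit_participant()` maximises each participant's summed log choice
probability. Because the likelihood surface can be multimodal in
$(\kappa, \eta, \lambda)$, a coarse grid — 5 evenly spaced points per free
parameter, with the $\lambda$ axis log-spaced over [0.1, 20] plus 0 —
selects the start for a bounded L-BFGS-B refinement (objective tolerance
about 1e-8; estimates clamped to the box to remove optimizer dust). The
refined optimum never falls below the best grid point; if the local search
fails, the grid point is returned and flagged. Bounds confine ideal points
near the token range: $\kappa \in [0, 10]$ for the diffusion family but
$[0, 2.5]$ for amplification (where `H*R` reaches 16), $\eta \in [0, 10]$,
$\theta \in [0, 1]$, $\lambda \in [0, 20]$. A participant who never
compensates (all decisions 0) is flagged and excluded from modelling — at
the boundary the parameters are not reliably estimable.

Softmax probabilities are computed with max-subtraction so large
$\lambda U$ cannot overflow; $\lambda = \infty$ is accepted as the uniform
distribution over the argmax set, and the simulators resolve exact ties
(half-integer ideal points) to the larger token amount, the same
round-half-away-from-zero convention used when discretising Likert
ratings.

Models are compared by per-participant BIC,
$k \ln(n_{trials}) - 2\,\mathrm{logLik}$, summed over the cohort
(fixed-effects model comparison; the package reports one winner for the
sample, and random-effects model selection is out of scope). Exact ties
break toward fewer free parameters. $\lambda$ always counts as free, so
k is 4 for x.1, 3 for x.2 and x.3, and 2 for x.4.

## Validation by simulation

`predictive_accuracy()` simulates each participant's decisions from their
fitted parameters (50 sets by default), scores the proportion matching the
observed decisions, and tests the cohort mean against the chance level of
1/11 (9%) with a one-sample t test; the CI across participants is a t
interval. `parameter_recovery()` re-simulates and refits per set and
correlates generating with recovered parameters across participants,
summarising by the mean over sets with a 95% percentile interval. In an
applied run the "generating" values are the real-data estimates; in a
synthetic run the package correlates against the true generating
parameters, which is the stricter, self-contained reading.
`parameter_independence()` reports the Pearson correlation between
$\kappa$ and $\eta$.

One honest limitation: with deterministic agents ($\lambda \to \infty$)
the integer decisions identify $(\kappa, \eta)$ only up to the set of
values whose ideal points round to the same decisions — an identifiability
granularity of roughly ±0.1–0.15 in either parameter on the 64-trial
schedule. Noise-free refits therefore agree with the generating values at
that granularity (while reproducing every decision exactly), not to
arbitrary precision. Relatedly, at the documented stochastic cohort
($\lambda = 2$) the baseline $\eta$ carries more estimation noise than
$\kappa$ relative to its population spread, which caps its recovery
correlation slightly below $\kappa$'s.

## The synthetic cohort

The generator's defaults are the package's documented study conditions,
not tuning knobs:

* **Decisions**: model 1.3 agents with $\kappa \sim U(0.5, 4)$,
  $\eta \sim U(0, 3)$, $\lambda = 2$ (and $\theta \sim U(0, 0.5)$ for
  self-interest variants). The ranges keep ideal points inside the 0–10
  token scale for most cells; $\lambda = 2$ produces clearly structured
  yet stochastic choices. No population distribution is implied by the
  task itself; these are artifact choices, exposed in the config.
* **Emotions**: per-cell ratings
  `intercept + slope_H * H + slope_R * R + noise`, rounded half away from
  zero and clipped to 0–10. Fixed slopes default to the reference values
  0.74 (harm → guilt), 0.23 (harm → shame), 0.57 (responsibility → guilt)
  and 0.93 (responsibility → shame); intercepts 0.5 and 0.9 roughly
  equalise mean guilt and shame. Participant heterogeneity uses intercept
  SD 0.8 and slope SD 0.3 with residual SD 0.8: slope SD 0.3 makes
  individual slopes span a plausible 0–1.5 rating units per level while
  remaining recoverable from 16 cells, and residual SD 0.8 is typical
  single-item Likert noise. Ratings are generated once per cell, as
  surveyed, and broadcast to the four trials of the cell for the
  compensation regressions.
* **Emotion-mediated decisions** (for the regression stages):
  `D = round(1 + 0.22 * guilt + 0.10 * shame + noise)`, clipped, using the
  reference compensation weights.
* **Manipulation checks**: linearly increasing means (pain 2/4/6/8 on
  0–10; responsibility 3/4.5/6/7.5 on 1–9, correct-estimate mean 1.5) with
  participant intercept SD 0.6 and residual SD 0.8.
* **Traits**: independent Gaussians unless explicitly coupled to mean
  compensation.

What passing tests on these cohorts show is that the pipeline recovers
what the generator put in under the stated noise; they do not certify
behaviour on real data, whose emotion dynamics (e.g. trial-order effects,
scale-use habits, skewed ratings) the linear-with-Gaussian-noise generator
does not emulate.

## Behavioural statistics

Manipulation checks are pairwise two-level repeated-measures ANOVAs
computed from paired differences, for which `F = t^2` with df (1, n−1) and
partial $\eta^2 = t^2 / (t^2 + n - 1)$ — an identity the tests verify.

The emotion regressions are linear mixed models (via `lme4`/`lmerTest`,
maximum likelihood) of rating on the numeric level (1–4), emotion type and
their interaction, with participant random intercepts and random slopes
for each fixed effect. Emotion type is coded guilt = 1, shame = 0, so the
interaction coefficient is directly the guilt-minus-shame slope
difference; simple slopes per emotion are tested as linear contrasts with
Satterthwaite degrees of freedom (printed denominator dfs from other
software need not reproduce exactly, since the df approximation is
implementation-dependent). If the full random structure fails to converge
or is singular the model falls back to diagonal random effects, then to a
random intercept, and as a last resort (degenerate data such as the
noise-free limit) to OLS; the fallback level is recorded in the output.

The compensation family regresses tokens given on guilt (I), shame (II),
both (III) or both plus interaction (IV), with matching random slopes, and
selects by BIC (maximum likelihood fits, so fixed-effect structures are
comparable). The guilt-vs-shame contrast is a 1-df Wald chi-square on the
coefficient difference of the guilt + shame model, using the fitted
covariance.

`extract_sensitivities()` returns the six per-participant slopes used as
individual-difference measures (harm/responsibility → guilt/shame from
per-emotion models `rating ~ harm + responsibility`; guilt/shame →
compensation from the guilt + shame model). Each is the fixed effect plus
the participant's conditional mode (BLUP) — shrinkage-stabilised; when a
model fell back to a structure without random slopes, per-participant OLS
slopes are substituted and flagged in the `method` attribute.

Two generic inferential tools round out the stage: the classical
Pearson–Filon Z for comparing two dependent overlapping correlations, and
percentile-bootstrap mediation (5000 resamples by default) whose indirect
effect `a*b` is recomputed on every resample; both are validated by
type-I-error and coverage simulation in the test suite.

## Problem sizes and numerical choices

The package's own validation runs use 40-participant cohorts with 50
simulation sets for recovery, 10 replicate cohorts for model recovery,
1000 replicates for the Z-test size check and 500 for mediation coverage
(1000 resamples per replicate); unit tests use smaller cohorts. Softmax
normalisation is exact over the 11 options (no sampling), seeds are
derived from one master seed per run so every artifact is reproducible,
and CSV/JSON/YAML are the only interchange formats.

## A worked example

```{r, eval = FALSE}
ds <- simulate_dataset(participants = 20, seed = 1)
fits <- fit_cohort(ds$trials, models = model_ids())
cmp <- compare_models(fits)
cmp$winner

wfits <- fits[fits$model == cmp$winner & !fits$excluded, ]
val <- validate_model(utility_model(cmp$winner), wfits, ds$trials,
                      n_sets = 20, seed = 2)
val$accuracy$mean_accuracy

merged <- merge_emotions(ds$trials, ds$emotions)
compensation_regression(merged)$winner
```
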
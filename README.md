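# moralcomp

Computational modelling of guilt- and shame-driven compensation in a
4 × 4 harm × responsibility interpersonal game.

## The problem

When someone contributes to harming another person, how much do they pay to
make it right? Two cognitive antecedents plausibly drive the felt
obligation: the severity of the harm (`H`, four levels) and the person's
share of responsibility, manipulated through the number of wrongdoers `W`
(responsibility level `R = 5 - W`). Felt guilt and shame then convert that
appraisal into monetary compensation `D` (0–10 tokens from a 10-token
endowment). `moralcomp` is for researchers who want to fit, compare and
validate utility models of this decision, and to estimate per-participant
emotion and compensatory sensitivities with mixed-effects regressions — all
testable end to end on synthetic cohorts, with no data download.

## The models

Eight utility models cross two integration hypotheses with two optional
components. The *diffusion* family divides harm among the wrongdoers
(`A = H/W`, the average harm the decider is answerable for); the
*amplification* family multiplies harm by responsibility (`A = H·R`). The
full model in each family is

    U(D) = θ·(10 − D) − (1 − θ)·|κ·A + η − D|

with greed `θ` weighting self-interest against improper-compensation
aversion, compensatory sensitivity `κ` (tokens per unit of attributed
harm) and compensatory baseline `η` (tokens given unconditionally);
reduced variants drop `θ` and/or `η`. Utilities become choice
probabilities through a softmax with inverse temperature `λ`. Participants
are fitted by maximum likelihood (coarse-grid start + bounded
quasi-Newton), models compared by summed BIC, and the winner validated by
simulation: predictive accuracy against the 1/11 (9%) chance level,
parameter recovery across 50 simulated refits, and the κ–η independence
correlation. The behavioural-statistics stage implements the
repeated-measures manipulation checks, the emotion and compensation
mixed-effects regression families with BIC selection and a Wald
guilt-vs-shame coefficient comparison, per-participant sensitivity
extraction (BLUPs), Pearson–Filon tests for dependent correlations,
percentile-bootstrap mediation and trait correlations.

## A worked example

```r
library(moralcomp)

ds   <- simulate_dataset(participants = 20, seed = 1)  # model-1.3 agents
fits <- fit_cohort(ds$trials, models = model_ids())
cmp  <- compare_models(fits)
cmp
#> Model comparison over 20 participants; winner: 1.3
#>  model k bic_sum delta_bic n_participants
#>    1.3 3 2747.55     0.000             20
#>    1.1 4 2845.99    98.443             20
#>    2.3 3 3429.70   682.150             20
#>    ...

wfits <- fits[fits$model == cmp$winner & !fits$excluded, ]
val <- validate_model(utility_model(cmp$winner), wfits, ds$trials,
                      n_sets = 20, seed = 2)
round(val$accuracy$mean_accuracy, 3)   #> 0.486  (chance 0.091)
round(val$recovery$r_kappa$mean_r, 3)  #> 0.994
round(val$recovery$r_eta$mean_r, 3)    #> 0.987
round(val$independence$r, 3)           #> 0.237  (p = 0.314)
```

The comparison table says the generating diffusion-with-baseline model
(1.3) beats every rival by a large BIC margin on its own cohort; the
validation numbers say the fitted model predicts held-out simulated
choices five times better than chance, that both parameters are
recoverable nearly perfectly, and that κ and η do not trade off. The
regression stages run the same way from the bundle
(`emotion_regression(ds$emotions, "harm")`,
`compensation_regression(merge_emotions(ds$trials, ds$emotions))`), and
`run_pipeline(pipeline_config(seed = 1), "out/")` executes everything in
one reproducible pass.

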
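# metacrowd

Does asking crowd workers *how sure they are* make a crowd smarter?

`metacrowd` is an R package for studying two-choice crowdsourcing systems in
which users report a graded confidence judgment alongside every answer. It
compares the conventional design — screen users on a performance pre-test and
aggregate answers by **majority voting (MV)** — against a confidence-based
design that screens users on **metacognitive sensitivity** and aggregates by
**confidence-weighted majority voting (WMV)**. The package provides the
generative decision model, the metacognition score, exact and closed-form
expected crowd errors, population-level simulation sweeps, and a resampling
evaluation pipeline for trial-level behavioral data, plus a synthetic-cohort
generator so every stage runs without access to human data.

## The model

Each user is an equal-variance signal-detection agent. On a question whose
true answer is option *i* ∈ {1, 2}, the user draws evidence

> x | A = i  ~  N(μᵢ, σᵢ²)

and answers option 1 iff x ≤ c₁ (the Type I decision). Confidence (the
Type II decision) is read from the same evidence through ascending
per-choice thresholds on |x − c₁|, reported on a discrete 1..c_max scale
(default 5). The user's expected accuracy is

> Perf = Pr(A=1)·[1 − Q((c₁−μ₁)/σ₁)] + Pr(A=2)·Q((c₁−μ₂)/σ₂),

with Q the Gaussian upper-tail function. In the canonical parameterization
(c₁ = 0, σ = 1, μ₂ = −μ₁ = d/2) accuracy determines the separation d
exactly: d = 2·Φ⁻¹(Perf).

Metacognitive sensitivity is scored by **AUROC2**, the area under the
Type II ROC: sweep the confidence scale, tabulate hit rate
Pr(high confidence | correct) against false-alarm rate
Pr(high confidence | incorrect), and integrate by trapezoid. Three
confidence *archetypes* bracket the range: `high` (confident exactly when
correct, AUROC2 = 1), `medium` (constant confidence, AUROC2 = 0.5), and
`low` (confident exactly when wrong, AUROC2 = 0).

For a crowd of N users, the expected MV error conditional on each truth
side follows the Poisson-binomial distribution of second-option votes
(computed exactly), or its normal approximation with per-user moments
m = Σₙ pₙ, s² = Σₙ pₙ(1−pₙ). The WMV crowd errs when the signed
confidence-weighted sum Σₙ rₙcₙ lands on the wrong sign; its expected error
uses the per-user moments of rₙcₙ (exact convolution also available).

## Worked example

Simulate one agent, score it, then compare the two crowd designs on a
random population before and after a metacognition filter:

```r
library(metacrowd)

agent <- symmetric_params_from_performance(0.75, archetype = "high")
tab <- simulate_trials(agent, truths = rep(c(1L, 2L), 100), seed = 1)
mean(tab$truth == tab$response)   # 0.77  — near the configured 0.75
auroc(tab, "type2")               # 1     — the "high" archetype's AUROC2

pop <- sample_population(population_spec(), seed = 1)
compare_systems(pop)
#>   err_rebacs err_cobacs n_users_after_filter method
#> 1     0.0639     0.0134                  100 analytic_normal

compare_systems(apply_filters(pop, filter_spec(min_meta = 0.6)))
#>   err_rebacs   err_cobacs n_users_after_filter method
#> 1      0.481  0.000000760                   40 analytic_normal
```

`err_rebacs` is the expected error of the majority-vote system and
`err_cobacs` that of the confidence-weighted system. On this unfiltered
population the weighted crowd happens to win; after keeping only users with
AUROC2 ≥ 0.6 (the high-metacognition archetype) the weighted crowd is
essentially always right, while the plain majority — now a smaller crowd
selected on a criterion irrelevant to it — does far worse.

Sweeping many random populations shows the population-level picture:

```r
sw <- population_sweep(population_spec(), 1000, seed = 1)
tidy(sw)
#>   min_performance min_meta n_populations n_viable frac_cobacs_better ...
#> 1               0        0          1000     1000               0.46
```

Without any filtering the two designs are near parity: the weighted system
wins in about half of random populations. `autoplot()` methods visualize
sweeps and filter evaluations; `resample_filter_evaluate()` runs the
resampled 12-filter evaluation on trial-level CSV data (see
`vignette("confidence-weighted-crowds")`).

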
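---
title: "Confidence-weighted crowds: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted crowds: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacrowd)
library(dplyr)
```

`metacrowd` asks a concrete design question about two-choice crowdsourcing:
if users report a graded confidence with every answer, is a crowd that is
*screened on metacognitive sensitivity* and *aggregated by
confidence-weighted majority voting* more accurate than the conventional
crowd screened on a performance pre-test and aggregated by plain majority
voting? This vignette explains the generative model, the two aggregation
systems and their expected-error computations, the simulation and
resampling studies built on them, and the numerical and design choices
made along the way.

## The decision model

Every user is an equal-variance Gaussian signal-detection agent. On a
question whose correct answer is option $i \in \{1, 2\}$, the agent draws a
decision variable $x \mid A{=}i \sim \mathcal{N}(\mu_i, \sigma_i^2)$ and
answers option 1 iff $x \le c_1$. The expected accuracy is

$$
\mathrm{Perf} = \Pr(A{=}1)\bigl[1 - Q\bigl(\tfrac{c_1-\mu_1}{\sigma_1}\bigr)\bigr]
              + \Pr(A{=}2)\,Q\bigl(\tfrac{c_1-\mu_2}{\sigma_2}\bigr),
$$

with $Q(z) = \Pr(Z > z)$ the standard normal upper tail. Because only the
distances between the $\mu_i$ and $c_1$ matter, the package works in the
canonical parameterization $c_1 = 0$, $\sigma = 1$, $\mu_{1,2} = \mp d/2$,
where accuracy pins down the separation exactly:
$d = 2\,\Phi^{-1}(\mathrm{Perf})$
(`symmetric_params_from_performance()`). Accuracies below one half give a
negative $d$ — a systematically wrong user — which matters for the
population studies below. One convention is used everywhere downstream:
"$x \le c_1$ means option 1", and the per-user probability of a
*second*-option vote on truth side $i$ is $Q(-\mu_i)$. (The alternative
sign that sometimes appears in informal derivations is inconsistent with
the accuracy formula at $c_1 = 0$; we use $Q(-\mu_i)$ throughout.)

The confidence report (the Type II decision) reads the same evidence
through ascending per-choice thresholds on the strength $|x - c_1|$,
yielding an integer level $1..c_{\max}$ (default $c_{\max} = 5$; the
default ladder spaces thresholds 0.5 SD apart). Three deterministic
*archetypes* replace the threshold rule when set:

* `high` — maximum confidence when correct, minimum when wrong (AUROC2 = 1);
* `medium` — the middle level always (AUROC2 = 0.5);
* `low` — minimum confidence when correct, maximum when wrong (AUROC2 = 0).

Archetypes are deterministic because they are specified by their behavior,
not by a distribution; an optional `lapse` probability replaces a report
with a uniform level, softening archetype AUROC2 away from the exact
endpoints when graded scores are wanted. The analytic joint law of
(response, confidence) for any agent and truth side is available as
`response_confidence_pmf()`, and is the basis of every closed-form
confidence-weighted moment.

## Scoring metacognition

Metacognitive sensitivity — how well confidence separates a user's own
correct from incorrect answers — is scored by AUROC2: sweep the thresholds
$t = c_{\max}..2$, compute the Type II hit rate
$\Pr(\text{conf} \ge t \mid \text{correct})$ and false-alarm rate
$\Pr(\text{conf} \ge t \mid \text{incorrect})$, anchor at $(0,0)$ and
$(1,1)$, and integrate by the trapezoid rule. The integrator choice is
ours (the score is conventionally named but the integration scheme rarely
stated); trapezoid with fixed anchors makes the score exactly invariant
under strictly monotone relabelings of the confidence scale and maps
confidence reversal to $1 - \mathrm{AUROC2}$.

A participant with no correct or no incorrect trials has no measurable
discriminability. We return `NA` rather than a silent number, and such
users fail any metacognition filter with a positive threshold. How real
analyses handle these cases is usually unreported; an explicit sentinel
keeps the policy visible in every downstream report.

## Two crowds, two expected errors

With votes coded 0/1 (or signed $\pm 1$), plain majority voting answers
the second option exactly when at least half the votes say so — ties
resolve to the second option, and the same tie rule is used in the
weighted system so that the two coincide whenever confidences are constant
(a property the test suite enforces on random inputs).

For the expected MV error, the count of second-option votes conditional on
truth side $i$ is a sum of independent, generally non-identical Bernoulli
variables — a Poisson-binomial. The package evaluates it two ways:

* **exactly**, by the $O(N^2)$ convolution (`mv_error_exact()`), including
  the tie atom at $N/2$;
* **normal approximation** with per-user moments $m_i = \sum_n p_{i,n}$,
  $s_i^2 = \sum_n p_{i,n}(1-p_{i,n})$, reading the error as the normal
  mass on the wrong side of $N/2$ while retaining the range-truncation
  terms at $0$ and $N$.

A homogenized closed form, `mv_error_normal(mu_bar, ...)`, which collapses
the population to a single mean-evidence pair before applying $Q$, is also
exported and matches the exact path on homogeneous populations (within
0.01 at $N = 101$ across an accuracy grid — a tested property). For
heterogeneous populations we deliberately do **not** homogenize:
$Q$ is convex over half its domain, so plugging the average evidence into
$Q$ biases the vote probability (by Jensen's inequality) badly when the
population spans accuracies from 0.1 to 1. Summing per-user moments is the
central-limit-correct treatment for independent non-identical summands and
converges to the exact Poisson-binomial answer; `compare_systems()`'s
analytic path uses it for both systems.

The confidence-weighted crowd errs when the signed weighted sum
$\sum_n r_n c_n$ lands on the wrong sign. Weights are the raw integer
levels $1..5$ — no normalization, matching how a deployed system would
multiply reported levels directly. The expected error again comes in two
flavors: a normal approximation from the per-user moments of $r_n c_n$
(`wmv_error_normal()`), and an exact convolution over the integer support
$\{-c_{\max},..,-1,+1,..,c_{\max}\}$ per user (`wmv_error_exact()`), which
costs $O(N^2 c_{\max}^2)$ and serves as the oracle for the approximation.
For archetype agents the moments have closed forms: for example a `low`
user with accuracy $p$ has $E[rc \mid A{=}{+1}] = 6p - 5$, negative until
$p > 5/6$ — a decent-accuracy crowd of such users is *systematically*
driven to the wrong answer, which is exactly why a metacognition filter
matters.

Degenerate cases are handled by limits, not division failures: zero
variance collapses the normal to a point mass and the error to an
indicator. All errors are clipped to $[0, 1]$.

## The population study

`population_spec()` fixes the simulated study conditions: 100 users, 200
questions, equal priors, per-user accuracy drawn uniformly on $[0.1, 1)$,
and archetypes drawn uniformly. The support reaching down to 10% accuracy
reflects the regime of interest — populations that include systematically
wrong users — and uniform mixing is the neutral choice where nothing more
specific is known; both are configurable. `population_sweep()` samples
many such populations, applies each filter in a grid
(`filter_spec(min_performance, min_meta)`), computes both expected errors
analytically per population, and reports per filter the fraction of
*viable* populations (at least one survivor) where the weighted system's
error is strictly lower — ties count as not-better. With no filter and
10,000 populations the better-fraction lands near 50%: without screening,
confidence weighting is no panacea, because low-metacognition users hurt
the weighted crowd as much as low-performance users hurt the plain one.
With a metacognition filter high enough to keep only high-archetype users,
the weighted crowd dominates — the directional claim the acceptance tests
assert.

Analytic errors keep a 10,000-population sweep to about a minute on one
CPU; `method = "monte_carlo"` exists for validation and is tested to agree
with the closed forms within three binomial standard errors at 20,000
simulated questions. Sweeps are bit-for-bit reproducible under a fixed
seed: every stochastic entry point takes an explicit integer `seed`,
scopes it with `withr::local_seed()`, and restores the caller's RNG state.

## The behavioral pipeline

`read_trials_csv()` ingests trial-level data (participant, task, trial
index, truth, response, confidence, optional response time, category and
self-estimate), validating option codes, confidence range and per-task
trial ordering, and reporting offending line numbers. Scores follow the
two-task logic: the performance score is accuracy over the first 30
tweet-task trials (a short pre-test whose predictive value is checked by
`split_half_correlation()` against the remaining 70), and the
metacognition score is the memory-task AUROC2 — a deliberately different
task, leaning on the domain-generality of metacognitive ability, which is
what makes one-time metacognitive screening attractive in the first place.

`resample_filter_evaluate()` is the end-to-end evaluation: repeatedly
sample 60% of participants without replacement (fraction-based,
`floor(0.6 N)`, configurable), apply each of the 12 coupled filters
(performance 0.4/0.5/0.6/0.7 crossed with metacognition 0.5/0.6/0.7) to
the *same* sampled society, and score the surviving crowd on the held-out
tweet trials 31–100 under both MV and WMV. Repetitions with no survivors
record `NA` — reported, never imputed, and rendered as "–" in the printed
table. Per filter, a one-tailed paired t-test asks whether the MV error
exceeds the WMV error across the (by default 100) repetitions; because it
is ambiguous whether such tests should pair repetitions per filter or pool
across filters, both are computed (`tidy()` gives the per-filter tests,
`glance()` the pooled one). The paired t statistic is computed by the
direct formula so that the all-zero-difference case can follow the
$t = 0, p = 0.5$ convention; `stats::t.test` is the cross-check oracle in
the tests on non-degenerate input.

`dk_calibration()` bins participants by end-of-task self-estimate against
realized accuracy (the Dunning–Kruger summary), and
`confidence_rt_correlation()` computes per-participant Pearson
correlations between confidence and response time with counts of negative
and significantly negative participants. `label_tweet_gender()` implements
the stimulus-preparation rule: a tweet's perceived gender is the side
exceeding 60% of votes (otherwise undecided), a tweet is *simple* iff
perceived matches actual, and an account is simple iff a strict majority
of its tweets are.

## The synthetic cohort generator

Because the human dataset behind the two tasks is not publicly archived,
`generate_cohort_trials()` emulates their *statistical structure* so the
whole pipeline runs and is testable: 86 participants; a 200-trial
recognition memory table per participant (balanced old/new) generating
confidence via the participant's archetype; and a 100-question tweet table
in four balanced gender-by-difficulty categories, the first 30 questions
balanced 15/15 by gender, with one fixed presentation order per cohort.
Task accuracies are drawn from truncated normals matching the observed
bands of the two tasks — memory $\mathcal{N}(0.675, 0.074)$ on $(0.5, 1)$,
tweet $\mathcal{N}(0.618, 0.046)$ on $(0.45, 0.95)$. Difficulty is modeled
as discriminability: "complicated" categories multiply each agent's
separation $d$ by 0.5, since topic-based gender ambiguity is, in model
terms, reduced evidence. Response times follow
$\mathrm{rt} = 4000 - 400\,c + \mathcal{N}(0, 800^2)$ ms, floored at
200 ms — a coarse stand-in for the empirical confidence–RT link, not a
process model. Self-estimates are either `calibrated` (accuracy plus small
noise) or `dk_biased` (compressed toward 0.575 with slope 0.3), the latter
qualitatively reproducing the classic miscalibration pattern.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: human metacognition is graded (empirical
AUROC2 clusters around 0.55–0.65, not at the archetype endpoints 0/0.5/1);
confidence, accuracy and response times covary trial-by-trial through
evidence strength rather than a linear rule; there is no learning,
fatigue, bias drift, or item-level difficulty beyond the two-level
category factor; and no stimulus content exists at all. Conclusions about
*directional* system behavior (e.g. that metacognitive screening helps the
weighted crowd) transfer; quantitative error levels do not.

## Numerical choices and limitations

* **Tie-breaking**: both aggregation rules resolve ties to the second
  option, so constant-confidence equivalence is exact.
* **Odd crowd sizes in validation**: closed-form-versus-simulation checks
  use $N = 101$; with odd $N$ the half-count threshold falls between
  integers, which removes the tie atom and makes the untruncated normal
  approximation accurate to well under 0.01.
* **Problem sizes**: the shipped studies use 10,000 sampled populations,
  20,000-question Monte-Carlo validations, and 100-repetition resampling —
  sizes at which the assertions' tolerances (three standard errors) are
  meaningful while a full run stays within a coffee break on one CPU.
* **Seeds**: required, integer, scoped; unseeded stochastic calls are
  rejected rather than silently non-reproducible.
* **Undefined values** (degenerate AUROC2, zero-survivor repetitions,
  empty populations) propagate as `NA` sentinels and are visible in all
  reports.

Known limitations: the equal-variance Gaussian model excludes
unequal-variance and non-Gaussian evidence as well as any response-time
process model; confidence weights are raw levels (no calibration or
normalization layer); the analytic weighted-crowd error assumes
independent users (no correlated errors or herding); and the archetype
trichotomy is a simulation device, not a claim about the empirical
distribution of metacognitive ability.
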
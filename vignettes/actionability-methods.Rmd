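---
title: "Measuring model actionability as entropy reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring model actionability as entropy reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionability)
```

## The problem

Traditional performance metrics for multiclass clinical prediction models
(AUROC, F1, calibration) say little about whether a model would actually
help a clinician decide. One pragmatic, early-development lens is
*actionability*: does the model tend to reduce the uncertainty a clinician
faces, relative to clinician judgment alone? This package quantifies that
tendency with Shannon entropy applied to the two probability distributions
at the heart of a decision episode, framed as a partially observable Markov
decision process (POMDP):

1. **Diagnosis phase.** The belief over underlying states $s_t \in S$
   (the differential diagnosis) given observations $o_t$. For a belief
   $p(s_t \mid o_t)$ its uncertainty is
   $H = -\sum_{s_t \in S} p(s_t \mid o_t)\,\log p(s_t \mid o_t)$.
   The diagnosis-phase actionability of a candidate model against a
   reference (by default the clinician-alone beliefs, but any model can be
   the reference) is the per-sample entropy difference
   $\Delta^s_i = H^s_{0,i} - H^s_{m,i}$, averaged over the test cohort.
   Positive $\Delta^s$ means the candidate leaves less diagnostic
   uncertainty.

2. **Action phase.** Given a transition model $p^*(s_{t+1} \mid s_t, a_t)$
   (the benefit:risk structure of each treatment in each state) and a
   policy $\pi(a_t \mid s_t)$, the induced future-state distribution is the
   policy-weighted mixture
   $p(s_{t+1} \mid s_t) = \sum_{a_t \in A} p^*(s_{t+1} \mid s_t, a_t)\,
   \pi(a_t \mid s_t)$.
   The action-phase actionability $\Delta^a$ compares the uncertainty of
   the reference policy's future distribution $p_0$ with the candidate
   policy's $p_m$, per sample, then averages.

Both metrics are screens for *early* model development, upstream of
calibration assessment and of decision-curve analysis; the package
therefore also ships the standard net-benefit computation as a companion
(see below), without combining the two into a single score — how the two
should be jointly summarized is an open research question, so the report
juxtaposes them.

## The two readings of the action-phase candidate term

The candidate term of $\Delta^a$ admits two readings, and they differ
materially:

* **self_entropy** (default): the candidate term is $H(p_m) = -\sum p_m
  \log p_m$, so $\Delta^a = H(p_0) - H(p_m)$ — a symmetric comparison of
  the two distributions' own uncertainties, consistent with comparing
  "the entropies of the future-state distributions with and without the
  model". Swapping reference and candidate negates $\Delta^a$.
* **as_printed**: the candidate term is the cross-entropy
  $-\sum p_0 \log p_m$. Algebraically
  $H(p_0) - \mathrm{CE}(p_0, p_m) = -\mathrm{KL}(p_0 \,\|\, p_m) \le 0$
  with equality iff $p_0 = p_m$: under this reading a candidate policy can
  *never* show positive actionability, and the metric instead penalizes
  divergence from the reference.

Because the second reading follows a formulation in which the reference
weights appear inside the candidate's logarithm, and the first follows the
stated intent, the package implements **both**, defaults to
`self_entropy`, records the mode in every result, and tests the
$-\mathrm{KL}$ identity explicitly. No silent choice is made; users who
want the divergence-penalty semantics get them by passing
`mode = "as_printed"`.

## Conventions and numerical choices

* **Log base.** Unspecified in the metric's usual presentation; the
  package defaults to base 2 so entropies read as bits ("yes/no questions
  left"), with any base > 1 available (`base = exp(1)` for nats). Entropy
  in nats is entropy in bits times $\ln 2$, and this identity is tested to
  1e-12.
* **$0 \log 0 := 0$**, the standard information-theoretic convention.
* **Probability validation.** Rows must be non-negative and sum to 1
  within `1e-8`; an opt-in `renormalize` flag divides by the sum when the
  deviation is within tolerance (elicited clinician probabilities rarely
  sum exactly to 1). Negative entries are never repaired.
* **Unsupported zeros.** Cross-entropy with $q_i = 0$ where $p_i > 0$
  returns `+Inf` rather than raising, so cohort means flag the problem;
  per-sample infinities are additionally listed in the result's warnings.
  An optional `epsilon` floor in $(0, 10^{-3}]$ is available but off by
  default because flooring silently changes the metric.
* **Alignment.** Belief tables are matched by `sample_id`, never by row
  position, and candidate columns are permuted to the reference's state
  ordering; label matching is exact and case-sensitive. Downstream
  entropies are invariant to the input column order (tested).
* **Top-1 ties** in the stratified report break toward the lowest state
  index; the number of tied samples is reported alongside.
* **Temperature sharpening** in the generator is computed in log space
  with a max-shift, so extreme temperatures do not underflow.

## What the metric cannot see, and the stratified report

Entropy reduction is ground-truth-free. A degenerate model that always
outputs 100% for one diagnosis achieves the maximal $\Delta^s = \log_2 K$
whether or not it is ever right — it may simply be confidently wrong.
Two safeguards operationalize this known failure mode:

* `stratify_actionability()` partitions the cohort by whether the
  candidate's top-1 state matches the recorded true state and reports mean
  $\Delta$, mean candidate entropy and counts per stratum, so a
  high-$\Delta$/incorrect stratum is immediately visible;
* `full_report()` raises a *degenerate candidate* warning when more than
  50% of candidate beliefs are one-hot (an operational convention of this
  package; the threshold is configurable via `degenerate_threshold`).

True states never enter the metric itself.

## The synthetic scenario generator

No clinical data ship with the package; every analysis is testable through
a seeded generator that emulates the paired structure an actionability
assessment consumes:

* true states drawn uniformly over $K$ states;
* clinician reference beliefs drawn from a symmetric Dirichlet with
  concentration `reference_concentration` (default 1, uniform on the
  simplex), then tilted toward the sample's true state by multiplying that
  state's probability by `true_state_tilt` (default 2) and renormalizing —
  beliefs are informative about the truth but far from oracular, mirroring
  a differential diagnosis whose leading entry is frequently wrong;
* candidate beliefs as the reference beliefs sharpened at
  `candidate_temperature` (default 0.5): probabilities raised to the power
  $1/\tau$ and renormalized. $\tau = 1$ reproduces the reference exactly
  (so $\Delta^s = 0$ identically), $\tau < 1$ sharpens without changing
  any argmax — a controllable, monotone mechanism for "a model that
  reduces uncertainty relative to the clinician". Independent candidate
  beliefs can be had by generating a second scenario at a different seed;
* transition rows drawn from a symmetric Dirichlet
  (`transition_concentration`, default 1);
* a uniform reference policy (a maximally noncommittal clinician) and a
  one-hot candidate policy on the action maximizing the probability of a
  designated desired next state (default: the first state), so the two
  policies differ and the action phase has signal.

Defaults — 4 states, 3 actions, 500 samples — describe a moderately hard
multiclass problem at a test-set size typical of early model development,
and are the conditions under which the package's simulation-recovery
properties are stated: at $\tau = 0.5$ the mean $\Delta^s$ is positive in
every one of 50 seeded replicates, and the expected $\Delta^s$ is
non-decreasing as $\tau$ falls through $\{1.0, 0.8, 0.5, 0.25\}$.

**Seeding.** A single scenario seed feeds a fixed stream-splitting scheme:
each sample $i$ and each transition row gets a child seed from an affine
map of (seed, stream, index) modulo $2^{31}-1$, so enlarging the cohort
never perturbs earlier draws, and written scenarios are byte-identical
across runs with the same seed.

**What the generator does not emulate.** Real disease epidemiology,
costs, time-varying observations, inter-clinician disagreement, and
miscalibration patterns of real models are all out of scope. Passing the
simulation-recovery tests shows the metrics behave correctly under their
stated mechanism (a candidate that genuinely sharpens the reference), not
that any particular clinical model is actionable.

## Current states in the action phase

The action-phase metric conditions on the current state $s_t$, which is
unobserved at decision time in a real deployment. The package takes
current-state labels as input (in simulation, the ground truth), one per
test sample, and averages per-sample deltas exactly as the diagnosis phase
does. Since the future distribution depends only on the state, samples
sharing a state share a delta; averaging over samples weights states by
their cohort prevalence. A belief-weighted alternative
$\sum_s b(s)\, p(s' \mid s)$ is conceivable but is not implemented: it
changes the estimand from "uncertainty given the state" to "uncertainty
given the belief", and the package keeps the two phases' averaging rules
identical instead.

## Net benefit companion

Net benefit at threshold probability $t$ is
$\mathrm{NB}(t) = \mathrm{TP}/n - (\mathrm{FP}/n)\, t/(1-t)$, with
treat-all equal to $\pi - (1-\pi)\,t/(1-t)$ at prevalence $\pi$ and
treat-none identically zero; classification at $t$ is inclusive
(`prob >= t`). The formula is the standard one from the decision-curve
literature and is labelled as such in the report; it is included because
the actionability screen is explicitly positioned upstream of it.
`binarize_beliefs()` bridges the multiclass setting by designating one
state as positive. No calibration metrics are provided — calibration is a
separate, later evaluation step.

## Worked example

```{r example}
sc <- generate_scenario(scenario_config(n_samples = 200, seed = 42))

diag <- diagnosis_actionability(sc$reference, sc$candidate) |>
  bootstrap_mean_delta(n_boot = 1000, seed = 42)
glance(diag)

stratify_actionability(diag)

action_actionability(sc$transitions, sc$reference_policy,
                     sc$candidate_policy, sc$current_states) |>
  glance()

sc$candidate |>
  binarize_beliefs("s1") |>
  net_benefit(prob, outcome) |>
  glance()
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(diag)
```

## Problem sizes and reproducibility

The package's own test suite regenerates everything it checks: entropy and
marginalization against naive loop oracles (1,000 random draws each),
simulation recovery over 50 seeded replicates of 500-sample cohorts, and
byte-identical end-to-end CLI reproduction at matched seeds. The
`scripts/acceptance.R` driver recomputes the headline quantities on a
fresh 500-sample cohort from a user-supplied seed.

## Known limitations

* Entropy reduction is necessary-ish but not sufficient: a model can
  reduce entropy and be confidently wrong (hence the stratified report),
  and a clinically useful screening model may legitimately *increase*
  entropy for low-risk patients.
* The metric is sensitive to the sharpness of a model's output
  distribution, and therefore to modelling choices (temperature,
  label smoothing) that affect sharpness without affecting ranking.
* One-step lookahead only: no belief filtering over time, no multi-step
  rollouts, no policy optimization.
* Transition models and reference beliefs are accepted as given; their
  elicitation (from clinicians or retrospective cohorts) is out of scope,
  and elicitation error propagates unexamined into both metrics.
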
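# actionability

Entropy-based actionability metrics for multiclass clinical prediction
models, with a seeded synthetic scenario generator and a net-benefit
(decision-curve) companion.

## The problem

Most metrics used to report clinical ML performance (AUROC, F1,
calibration) do not say whether a model would help a clinician *decide*.
One early-development lens is **actionability**: a model's tendency to
reduce the uncertainty a clinician faces, relative to clinician judgment
alone. This package measures it at the two decision points of a POMDP-style
care episode:

**Diagnosis phase.** For each test sample, the Shannon entropy of the
candidate model's predicted diagnosis distribution is compared with the
entropy of a reference distribution (by default the clinician-alone
differential diagnosis; any model may serve as reference):

    H = -Σ_s p(s | o) log2 p(s | o)          (bits)
    Δs = mean_i [ H(reference_i) - H(candidate_i) ]

Positive Δs means the candidate leaves less diagnostic uncertainty.

**Action phase.** Given a transition model p\*(s'|s, a) and policies
π0(a|s) (reference) and πm(a|s) (candidate), each policy induces a
future-state distribution p(s'|s) = Σ_a p\*(s'|s, a) π(a|s); the per-sample
metric compares their uncertainties and averages:

    Δa = mean_i [ H(p0_i) - candidate_term_i ]

Two readings of the candidate term are implemented — the default
`self_entropy` (the candidate distribution's own entropy, H(pm)) and
`as_printed` (the cross-entropy -Σ p0 log pm, under which every per-sample
Δa equals -KL(p0‖pm) ≤ 0). See the methods vignette
(`vignettes/actionability-methods.Rmd`) for why both ship and neither is
chosen silently.

Because entropy reduction is ground-truth-free, a model can score highly
while being *confidently wrong*; `stratify_actionability()` and the
degenerate-candidate warning in `full_report()` expose exactly that
failure mode. Net benefit, NB(t) = TP/n − FP/n · t/(1−t) (standard
decision-curve literature), is included as the downstream companion the
actionability screen feeds into.

## Worked example

```r
library(actionability)

sc <- generate_scenario(scenario_config(n_samples = 200, seed = 42))

diag <- diagnosis_actionability(sc$reference, sc$candidate) |>
  bootstrap_mean_delta(n_boot = 1000, seed = 42)
diag
#> # diagnosis-phase actionability
#>   reference: clinician | candidate: candidate_ml | n = 200 | base = 2
#>   mean delta = 0.507638 bits
#>   95% bootstrap CI: [0.476113, 0.537075] (1000 resamples)
```

The candidate model resolves on average about half a bit of diagnostic
uncertainty per patient relative to the clinician-alone beliefs — roughly
half of one binary question answered — with a bootstrap interval well
above zero. Stratifying by correctness shows the reduction is *not* just
overconfidence, but also that it is larger on the samples the model gets
right:

```r
stratify_actionability(diag)
#> # A tibble: 2 × 6
#>   stratum       n mean_delta mean_candidate_entropy fraction n_top1_ties
#>   <chr>     <int>      <dbl>                  <dbl>    <dbl>       <int>
#> 1 correct      96      0.588                  0.866     0.48           0
#> 2 incorrect   104      0.433                  1.14      0.52           0

action_actionability(sc$transitions, sc$reference_policy,
                     sc$candidate_policy, sc$current_states) |>
  glance()
#> # A tibble: 1 × 9
#>   phase  mode         reference         candidate        n mean_delta ...
#> 1 action self_entropy clinician_uniform model_greedy   200      0.282 ...

sc$candidate |>
  binarize_beliefs("s1") |>
  net_benefit(prob, outcome) |>
  glance()
#> # A tibble: 1 × 5
#>       n prevalence n_thresholds max_model_nb best_threshold
#> 1   200      0.235           19        0.169           0.05
```

Per-sample values come from `tidy(diag)`; `autoplot(diag)` plots the
per-sample delta distribution, `autoplot()` on a `net_benefit()` result
draws the decision curve, and `full_report()` + `write_report()` emit a
versioned JSON document (schema in `inst/schema/`).

## Command line

A thin launcher wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","actionability.R",package="actionability"))')" \
  simulate --seed 7 --out scenario/
# then
... actionability.R diag --reference scenario/reference_beliefs.csv \
      --candidate scenario/candidate_beliefs.csv \
      --bootstrap 1000 --seed 7 --positive-state s1 --out report.json
... actionability.R action --transitions scenario/transitions.json \
      --reference-policy scenario/reference_policy.json \
      --candidate-policy scenario/candidate_policy.json \
      --states scenario/current_states.csv --mode self_entropy --out action.json
... actionability.R report --merge report.json action.json --out merged.json
```

Identical seeds give byte-identical files end to end.

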
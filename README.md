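# behavmet

Does resting metabolic rate explain how well an animal remembers, how bold it
is, or where it sits in its group's pecking order? `behavmet` implements the
complete analysis chain used to ask this question in small groups of juvenile
chickens — from raw respirometry gas traces to the final model-selection
table — together with a synthetic-data module that generates every input the
chain consumes, so the whole pipeline can be exercised and tested without any
field data.

It is aimed at behavioural physiologists and biostatisticians who work with
open-flow respirometry, radial-arm-maze assays, repeated personality assays
and dyadic dominance data.

## What it computes

**Resting metabolic rate (RMR).** Open-flow traces are corrected for ambient
baseline drift (linear interpolation between the opening and closing
baselines), a stable 5-min scoring window is chosen (minutes 13–18 of the
animal segment by default, shifted to the nearest stable window when the
trace is noisy), and rates come from the standard equations

    V̇O₂  = (FiO₂ − FeO₂) / (1 − FiO₂) × FR
    V̇CO₂ = (FeCO₂ − FiCO₂) / (1 − FiCO₂) × FR

with FR the flow rate; rates are mass-corrected by dividing by body mass.

**Short-term memory.** Radial-arm-maze trials are scored as revisit errors
and compared (one-sample, one-sided t-test) against two Monte Carlo nulls:
*random* choice — uniform arm draws until all arms are visited, whose error
count follows the coupon-collector law with mean `n·Hₙ − n` (13.7429 for 8
arms) — and *stereotypic* movement, a first-order Markov chain over arms
estimated from the observed transitions.

**Personality.** Repeatability of boldness and neophobia latencies is the
intraclass correlation `R = σ²ᵢ / (σ²ᵢ + σ²ₑ)` from a random-intercept
model, with a boundary-corrected likelihood-ratio test (50:50 χ²₀/χ²₁
mixture) and percentile confidence intervals from a parametric bootstrap.
Latencies are right-censored at 600 s and entered at the cap.

**Dominance.** Winner–loser tallies pooled over group trials are converted
to dyadic win proportions and ranked by David's score,
`DS = w + w₂ − l − l₂`, which sums to zero over the group.

**Model selection.** Whether metabolic rate (or personality) explains
errors, latencies or dominance is decided by the ΔAIC ≥ 2 rule: a candidate
model is preferred only if its AIC beats the simpler (null) model by at
least two points. Count models are negative binomial, latencies are censored
accelerated-failure-time models, dominance scores are linear models.

## Worked example

```r
library(behavmet)
cfg    <- run_config(seed = 42, repeatability = list(n_bootstrap = 1000))
report <- run_pipeline(cfg)
print(report)
```

```
==== Pipeline report (seed 42) ====
RMR: 72 traces, mean VO2 6.74 ml/min, VO2-VCO2 r = 0.997
Maze: 168 trials, observed mean errors 10.93
Observed vs random null: t(167) = -6.61, one-sided p = 2.497e-10
  observed mean 10.93 +/- 0.44, null mean 13.84 (n = 168 trials)
Observed vs stereotypic null: t(167) = -6.17, one-sided p = 2.436e-09
  observed mean 10.93 +/- 0.44, null mean 13.65 (n = 168 trials)
Repeatability:
  boldness_chick   R = 0.287 (CI 0.034-0.533, LRT p = 0.00209)
  boldness_block   R = 0.159 (CI 0.000-0.536, LRT p = 0.0459)
  neophobia_chick  R = 0.207 (CI 0.000-0.450, LRT p = 0.0181)
  neophobia_block  R = 0.129 (CI 0.000-0.482, LRT p = 0.0831)
Boldness-neophobia r = 0.259 (t = 2.24, p = 0.0281, n = 72)
Dominance: 920 interactions pooled over 6 trials
Model selection (dAIC rule):
  errors               dAIC =  -1.35 -> null
  boldness             dAIC =  -1.52 -> null
  neophobia            dAIC =  -0.09 -> null
  dominance            dAIC =   0.82 -> null
  vo2_time             dAIC = 229.22 -> time trend
  msvo2_time           dAIC = 321.38 -> time trend
  ...
```

Reading the output: the simulated chicks (memory-guided agents) make
significantly fewer maze errors than either null model predicts, both
personality traits are repeatable within individuals, raw V̇O₂ rises over the
study period — and, because the generator couples no behaviour to metabolic
rate by default, the ΔAIC rule retains the null model for every
metabolism–behaviour comparison. Setting a non-zero coupling in
`run_config(effects = ...)` flips the corresponding selection.

Individual stages are available directly: `correct_baseline_drift()`,
`select_window()`, `compute_vo2()`, `simulate_random_null()`,
`estimate_transition_matrix()`, `repeatability()`, `davids_score()`,
`compare_models()`, and so on; `inst/scripts/run_pipeline.R` wraps the whole
chain for shell use.

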
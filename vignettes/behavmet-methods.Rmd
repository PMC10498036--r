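---
title: "Methods: from gas traces to dominance ranks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gas traces to dominance ranks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavmet)
```

`behavmet` implements an analysis chain linking resting metabolic rate (RMR)
to short-term memory, personality and dominance in small animal groups, with
a synthetic-data module that generates every input the chain consumes. This
vignette is the package's own account of the models, the tunable parameters,
the numerical choices, and what the synthetic data do and do not establish.

## Open-flow respirometry

A session consists of an opening ambient baseline, the animal's chamber
trace and a closing baseline. Rates come from the open-flow equations

$$\dot{V}O_2 = \frac{F_iO_2 - F_eO_2}{1 - F_iO_2}\,FR, \qquad
  \dot{V}CO_2 = \frac{F_eCO_2 - F_iCO_2}{1 - F_iCO_2}\,FR,$$

where the incurrent fractions $F_i$ are the ambient baseline, the excurrent
fractions $F_e$ the chamber trace, and $FR$ the flow rate (ml min⁻¹). The
$\dot{V}O_2$ denominator deliberately omits a CO₂ term: in the emulated rig
water vapour and CO₂ are scrubbed before the O₂ analyser, and the equations
are implemented exactly in this two-term form. Fractions are used internally
on the 0–1 scale; percentages belong at I/O, divided by 100.

**Baseline drift.** Analyser and ambient drift is removed by linearly
interpolating the incurrent reference between the mean of the opening and
the mean of the closing baseline (anchored at each baseline's mid-time), per
gas. Linear drift of any magnitude is removed exactly by construction; the
residual error from using the opening-baseline mean in the denominator is
second-order (a drift of $10^{-4}$ in fraction units perturbs the
denominator by roughly one part in $8{,}000$).

**Scoring window.** Rates are averaged over a 5-min window, by default
minutes 13–18 of the 20-min animal segment. Stability is judged by the
windowed standard deviation of each gas over every candidate window on the
sampling grid; the default threshold is 3× the median windowed SD of the
segment, per gas — a scale-free criterion that adapts to the analyser's
noise floor. If the default window fails, the qualifying window whose start
is nearest the default start is used; if none qualifies, the globally least
unstable window is returned, always flagged `shifted_window`. The choice of
"nearest stable" as minimal $|\Delta\text{start}|$ is a design decision: the
operational definition used in practice is not standardised, and this is the
minimal-assumption reading.

Negative computed rates (possible under noise near zero exchange) are
clipped to zero with a warning rather than an error.

**The chamber model in the generator.** The chamber is treated as a single
well-mixed compartment, so excurrent fractions relax exponentially toward
the steady state obtained by inverting the equations above, with time
constant $\tau = V/FR$ — 7.5 min at the defaults (12 l, 1600 ml min⁻¹),
i.e. a flush-out of roughly 8 min. Because protocols of this kind keep each
bird in its chamber for the whole session while the analyser samples
chambers in turn, the generator exposes `occupancy_offset_min` (default 40):
the time the bird has already been inside when its recorded segment starts.
At the default the scoring window sits more than 7 time constants into
equilibration, which is what makes sub-0.1 % recovery of the injected rate
possible; a window opened immediately after chamber entry would still be
~13 % short of steady state, a property worth remembering when applying the
equations to real traces.

Generator defaults: ambient O₂ 0.2095, CO₂ 0.0004; linear drift $10^{-6}$
fraction min⁻¹ and Gaussian analyser noise SD $2\times10^{-6}$ — the order
of magnitude of a maintained field-gas analyser; CO₂ output at a respiratory
exchange ratio of 0.75, appropriate for post-absorptive (fasted) birds.

## Radial-arm maze and Monte Carlo nulls

A trial is an ordered sequence of arm visits ending when all `n_arms`
(default 8) have been visited; errors are revisits,
`length(visits) − distinct(visits)`. Two null models give the error count
expected without memory:

* **Random**: every arm equally likely at each step, immediate returns
  allowed. This is the coupon-collector process; the expected error count is
  $nH_n - n = 13.7429$ for 8 arms with variance $\sum_k (1-p_k)/p_k^2
  \approx 76.0$, so a 10 000-iteration simulation has Monte Carlo s.e.
  ≈ 0.087. Allowing immediate returns is a design decision: forbidding them
  gives $7H_7 - 8 \approx 10.15$, far from the value such simulations are
  known to produce, and the confinement mechanism in the emulated apparatus
  blocks re-entries physically, not probabilistically. The simulation draws
  the waiting time for each new arm directly from its geometric
  distribution, which is exact and fast; with a `visit_cap` the truncated
  path is reconstructed from the cumulative waiting times.
* **Stereotypic**: a first-order Markov chain over arms, estimated by
  pooling consecutive visit pairs over all trials and animals. The default
  mode is the literal 8×8 matrix ("probability of moving to an arm given the
  arm just visited"); a `relative_offset` mode pooling by
  $(\text{next}-\text{current}) \bmod n$ is available for sparse data. Rows
  never observed as a departure state fall back to uniform — the chain stays
  well-defined without pseudo-count inflation. Start arms are uniform by
  default; the empirical first-visit distribution is an option. Simulations
  are uncapped by default, with a safety bound (`max_steps`, default 10⁴)
  that turns absorbing chains into an explicit error.

Observed errors are compared with a null's mean by a one-sample t-test,
one-sided (`observed < null`), since the scientific question is whether
animals beat the no-memory baseline. With zero observed variance the test
degenerates to an exact comparison of means with p ∈ {0, 0.5, 1}.

**Memory agents.** The generator's win-shift agent picks, with probability
$\rho$ (`memory_fidelity`), uniformly among unvisited arms, otherwise
uniformly among all arms. Its expected error count is
$\sum_{r=1}^{n} \big(\rho + (1-\rho)\,r/n\big)^{-1} - n$ for $r$ the number
of unvisited arms. The pipeline default $\rho = 0.035$ makes this ≈ 11.6
errors per trial, the level of modest-but-real memory use that juvenile
chickens show on this task; individual variation enters as a logit-normal
spread (SD 0.5) around that value.

## Repeatability of latency traits

Latencies to leave a shelter (boldness: novel environment; neophobia: novel
object) are right-censored at 600 s and entered at the cap — the assignment
rule of the assay, kept for fidelity rather than treating the cap as
statistical censoring in the variance-component model. Repeatability is the
intraclass correlation $R = \sigma^2_{\text{ind}} / (\sigma^2_{\text{ind}} +
\sigma^2_{\text{res}})$ from the intercept-only random-intercept model,
fitted by REML. The pipeline fits on log latencies by default: latencies are
strictly positive and strongly right-skewed, and the generator defines its
ICC target on the log scale; the raw scale remains available
(`log_transform = FALSE`) since assay conventions differ.

The fitter is the package's own profiled likelihood for the one-way layout:
for a fixed variance ratio $\theta = \sigma^2_{\text{ind}} /
\sigma^2_{\text{res}}$ the GLS mean, the residual quadratic form and the
profiled residual variance are closed-form, leaving a one-dimensional
optimisation (performed on $u = \theta/(1+\theta) \in [0,1)$ so the boundary
is resolved accurately, with $\theta = 0$ checked explicitly as a boundary
candidate). On balanced designs the REML solution coincides with the
classical ANOVA estimators $\hat\sigma^2_{\text{res}} = \text{MSW}$,
$\hat\sigma^2_{\text{ind}} = (\text{MSB}-\text{MSW})/k$; on unbalanced data
the tests cross-check it against `lme4::lmer` to four decimals. The reason
for owning this fitter is speed: the parametric bootstrap and the
calibration studies in the test suite need on the order of $10^5$ refits,
which the closed-form profile delivers in seconds.

Significance uses a likelihood-ratio test of the random effect with ML fits;
because the null value lies on the boundary of the parameter space, the
reference distribution is the 50:50 mixture of a point mass at zero and
$\chi^2_1$. Confidence intervals are percentile intervals over parametric
bootstrap replicates (default 10 000 at the function level; the pipeline
default is 1 000, which stabilises the interval to about ±0.01 while keeping
a full run in seconds): data are re-simulated from the fitted model, refit,
and the R values collected; failed refits are counted and a warning raised
above 5 %.

Trait correlations are Pearson correlations over records paired by
individual × block × trial, with an option to drop pairs containing a
censored member — censored-at-cap values concentrate at a single point and
can manufacture correlation on their own. Note that a shared block effect
(both traits slower post-testing) also induces correlation between traits;
the pairing deliberately does not partial it out, matching how such
correlations are usually reported, but the generator makes the mechanism
easy to study.

## Dominance

Winner–loser tallies from repeated group trials are pooled element-wise
(scores on pooled tallies, not averaged per-trial scores — the default
reading when trials are short and sparse) and converted to dyadic win
proportions $P_{ij} = w_{ij}/(w_{ij}+w_{ji})$. Dyads that never interacted
contribute 0 in both directions rather than 0.5/0.5 — no information is
manufactured — and are counted in the output. The sample-size-corrected
index $D_{ij} = P_{ij} - (P_{ij}-0.5)/(n_{ij}+1)$ is available behind a
flag. David's scores are

$$w = P\mathbf{1},\quad w_2 = Pw,\quad l = P^{\top}\mathbf{1},\quad
  l_2 = P^{\top}l,\quad DS = w + w_2 - l - l_2,$$

which sum to zero over the group and are anti-symmetric under transposing
the win matrix; ties in the ranking are broken by identifier order and
flagged. The generator draws latent abilities $d_i \sim N(0,
\sigma^2_{\text{ability}})$, Poisson encounter counts per dyad and
Bradley–Terry outcomes $\Pr(i \text{ beats } j) = \text{logistic}(d_i -
d_j)$ — any transitive latent model would do; the logistic choice gives a
tractable rank-recovery oracle.

## Model selection

All explanatory models are compared by the ΔAIC rule: a candidate is
preferred only if its AIC undercuts the simpler model's by ≥ 2.00
(boundary inclusive); otherwise the simpler (null) model is retained.
Predictors are standardised to mean 0, SD 1 (sample, $n-1$ convention).

The mixed-effects machinery of the emulated analyses is deliberately
simplified to fully specified fixed-effects likelihoods: negative binomial
regression (log link — the conventional NB link; dispersion profiled by ML,
fixable for the Poisson limit) for error counts, Gaussian random-intercept
models fit by ML for time trends (the one place a random effect is kept,
via `lme4`; singular fits fall back to ordinary regression, flagged), and
censored accelerated-failure-time models for latencies. Every fit records
its deviations in the output.

**Where a predictor varies only between individuals** — mean mass-corrected
$\dot{V}O_2$, mean latencies — the pipeline tests it on individual-level
summaries: total maze errors per individual with a log-trials offset, and
the geometric-mean latency per individual (censored only if the animal never
left the shelter in any trial). Repeated trials of one animal are not
independent evidence about a between-individual predictor; with the random
effects simplified away, trial-level fits would inflate the evidence by the
design effect $1 + (m-1)\,\text{ICC}$ and select spurious predictors far too
often. Aggregation restores calibration at the level at which the predictor
varies. For the latency summaries the pipeline uses the log-normal AFT
family: geometric-mean latencies are log-normal to a good approximation, and
on the log scale that model is exactly Gaussian, whereas the Weibull
(Gumbel-on-log) family is misspecified there and measurably noisier in its
likelihood ratios. The Weibull remains the default of the exported
`fit_censored_latency_model()` for trial-level latency data.

A calibration bound worth stating: with $n = 12$ individuals, the ΔAIC ≥ 2
rule's false-selection probability for one superfluous parameter cannot be
pushed below $\Pr\{F_{1,10} > (n-2)(e^{4/n}-1)\} \approx 7.5\,\%$ for any
correctly specified ML model (it reaches the familiar ~4.6 % only
asymptotically). Null-model selection rates around 92–93 % per comparison
are therefore the honest ceiling at this design size, a property of the
rule, not of the implementation.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume —
washout dynamics and drift in gas traces, win-shift visit sequences,
log-normal censored latencies with individual intercepts, Bradley–Terry
contests — under the emulated study's design: 12 individuals, 6 respirometry
sessions each over days 21–41 (body mass growing from ~100 g, mass-specific
rate declining gently with age), 14 maze trials each, 3 + 3 latency trials
per trait in pre/post blocks with ICC targets 0.45 (boldness) and 0.31
(neophobia) and post-block shifts that raise latencies and censoring, and 6
dominance trials at ≈ 2.36 encounters per dyad per trial (≈ 930 interactions
in total). A single master seed fans out into independent per-stage streams,
so runs are bit-reproducible and changing one stage's settings leaves the
others' data untouched.

What it does not emulate: thermoregulatory or circadian structure in RMR,
within-trial latency dynamics, observation/scoring error in behavioural
tallies, non-transitive dominance, or the truncation pattern of real maze
trials that are stopped early (a `visit_cap` exists, but the matched
truncation distribution of stopped trials is unknown and not modelled).
Passing tests therefore certify the computational chain and its statistical
calibration under these assumptions, not the biology of any particular
dataset.

## Problem sizes and numerical choices

The test suite runs the Monte Carlo checks at the sizes the methods
prescribe where that is cheap (10⁴-iteration nulls; 1 000 score matrices;
10⁵ pooled transitions for matrix recovery) and scales calibration studies
to what they need rather than more: 200 replicates × 500 bootstraps for CI
coverage, 500 replicates for LRT size, 100 seeded end-to-end runs for the
null-selection pattern, with the maze iterations and bootstrap counts of
those end-to-end runs reduced since they do not enter the quantity under
test. Numerical tolerances follow the quantity: exact arithmetic identities
at 10⁻⁹–10⁻¹², cross-package agreement at 10⁻⁴, Monte Carlo quantities at
3 standard errors.

## Known limitations

* Censored latencies enter the variance-component model at the cap value;
  heavy censoring therefore compresses the residual variance and biases R —
  acceptable at the few-percent censoring rates of the emulated design,
  not beyond.
* The ΔAIC rule at 12 individuals is liberal (see the calibration bound
  above); conclusions of "no effect" are correspondingly conservative,
  conclusions of "effect" less so.
* The stereotypic null inherits the estimation error of the transition
  matrix; with few trials the uniform fallback rows pull it toward the
  random null.
* The respirometry model assumes perfect mixing and a constant flow rate;
  real chambers deviate, and the recovered rates are only as good as the
  washout assumption near the scoring window.
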
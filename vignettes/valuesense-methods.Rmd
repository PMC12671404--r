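---
title: "Methods: overall-value effects in two-alternative choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overall-value effects in two-alternative choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

In two-alternative forced choice, decisions between two *high*-valued
options are made faster than decisions between two *low*-valued options,
even when the difference between the options is held constant. This
*value-sensitivity* (or magnitude-sensitivity) of response times is well
established; what has been contested is whether the **overall value**
(OV, the sum of the two options' values) also changes **accuracy**.
Competing mechanistic accounts make opposite predictions: facilitated
processing implies faster *and more accurate* choices at high OV,
reduced caution or value-scaled noise implies faster *but less accurate*
choices.

`valuesense` packages the analysis pipeline for this question:

1. a trial-level data model with standardized OV and RV predictors,
2. per-study mixed-effects regressions of log RT and accuracy,
3. random-effects meta-analysis of the per-study OV coefficients
   (overall, by stimulus type, and against a binary moderator),
4. BIC-approximated Bayes factors for the OV effect on accuracy,
5. a Monte-Carlo simulator for the Leaky Competing Accumulator with
   collapsing decision thresholds (CB-LCA), the mechanistic model that
   can produce *faster and more accurate* choices at high OV, and
6. a synthetic-data generator standing in for the original trial-level
   datasets, which are not redistributable.

The package ships a 40-study coefficient table
(`load_table1_fixture()`; 5 abstract, 7 brightness, 7 numbers, 21
preference studies) from which the pooled estimates are reproduced
exactly; trial-level analyses run on synthetic corpora.

## Predictors and the data model

For each study, OV is `value_a + value_b` and RV is
`|value_a - value_b|`, both z-scored **within the study** across all
retained trials. Two conventions had to be fixed where the field's
descriptions are silent:

* z-scoring uses the **population** SD (divide by *n*). At study sizes
  of hundreds to tens of thousands of trials the distinction from the
  sample SD is negligible, but fixing it makes results bit-reproducible.
* z-scoring happens over the retained trials of the whole study, not
  per participant, and no outlier rule is applied (none is stated in
  the source analyses; rows with non-positive or missing RT or missing
  choice are dropped and counted, never imputed).

Accuracy is defined as choosing the option with the higher (stated)
value. On equal-value trials accuracy is therefore undefined: these
trials carry `NA` accuracy, are excluded from accuracy models, but are
retained for RT models — and they power a dedicated analysis, since an
RT decrease with OV *at equal values* cannot be explained by
difficulty confounds. A study enters the equal-alternatives analysis
only with strictly more than 50 equal-value trials.

When the raw value difference is constant across trials (some
perceptual designs), RV has no variance; `rv_z` is set to zero, the
models drop the RV terms, and the Bayes-factor null model reduces to
the intercept-only form.

## Per-study mixed models

For each study,

* RT model: `log(rt) ~ ov_z + rv_z + (1 + ov_z + rv_z | participant)`
  fitted by REML (`lme4::lmer`),
* accuracy model: the logistic analogue on unequal-value trials
  (`lme4::glmer`, Laplace approximation, bobyqa optimizer).

Coefficients are reported per SD of the standardized predictor;
p-values are Wald (normal approximation), with no Satterthwaite
correction — matching large-sample mixed-model reporting. Random-effect
correlations are estimated unstructured by default (`fit_config()` can
request a diagonal structure); the source analyses do not state the
correlation structure, and at the corpus scale the pooled estimates are
insensitive to it.

Mixed logistic models with random slopes routinely fail on small
studies, so a **fallback ladder** is applied and recorded in the
`method` column: (1) full random slopes; (2) random intercepts only;
(3) a two-stage estimator (per-participant regression, then a
precision-weighted mean across participants). "Convergence failure"
means an error, a non-zero optimizer status or non-finite standard
errors; boundary (singular) fits are accepted, as is standard. Studies
with fewer than 20 usable trials per outcome, a single participant, a
constant OV, or all-correct/all-error responses are skipped with a
logged reason; corpus runs never abort on a single study
(partial-results contract).

## Random-effects meta-analysis

Per-study OV coefficients `b_i` with standard errors `se_i` are pooled
under the additive random-effects model `b_i ~ N(mu, se_i^2 + tau^2)`
with inverse-variance weights `w_i = 1/(se_i^2 + tau^2)`:

* `pooled_b = sum(w_i b_i) / sum(w_i)`, `pooled_se = 1/sqrt(sum(w_i))`,
  z and two-sided normal p (no Knapp–Hartung adjustment),
* `tau^2` estimated by **REML** (primary; bounded one-dimensional
  optimisation of the restricted log-likelihood, tolerance 1e-10, with
  an explicit check of the `tau^2 = 0` boundary) or by
  **DerSimonian–Laird** as a cross-check,
* heterogeneity reported via Cochran's Q against chi-squared(k − 1).

REML is the dominant default of standard meta-analysis software, which
is why it is primary here; the tests additionally verify the estimator
against a brute-force grid maximizer of the restricted likelihood and
against `metafor::rma` on the packaged table. Subgroup analyses (by
stimulus type) fit each group independently with its own `tau^2`;
singleton groups are reported without heterogeneity. The binary
moderator analysis is a mixed-effects meta-regression with a 1-df Wald
(Q_M) test; the real per-study moderator flags ("cited in the
value-sensitivity literature") are not printed in the source table, so
that operation is exercised on synthetic flags only.

Fixture-based targets are asserted at the printed 3-decimal precision
with tolerances (±0.002 on pooled effects, ±0.01 on tau) that absorb
the rounding of the inputs and the estimator ambiguity.

## Bayes factors

For each study, H1 (`accuracy ~ ov_z + rv_z + RE`) is compared with H0
(`accuracy ~ rv_z + RE`, intercept-only fixed part when RV is
constant), with the **same** random-effects structure (random OV
slopes) in both, so the Bayes factor isolates the fixed OV effect. The
original Bayesian machinery (priors, sampler, marginal-likelihood
method) is unstated, so the package uses the Schwarz/BIC approximation
`bf10 = exp((BIC0 - BIC1)/2)`: prior-free, deterministic and
reproducible, at the cost of a known conservative bias for moderate
effects (it corresponds to a unit-information prior). Outputs are
flagged `approximation = "BIC"`, and the packaged table's printed BF
labels are not an acceptance surface. Labels follow the classical
five-band vocabulary — anecdotal (1, 3], moderate (3, 10], strong
(10, 30], very strong (30, 100], extreme (> 100), reciprocal bands for
H0, values exactly on a boundary take the weaker category, and
`bf10 = 1` maps to "No evidence".

## The collapsing-bound LCA

Two accumulators `x_1, x_2` start at 0 and evolve by Euler–Maruyama:

```
x_i <- max(0, x_i + (I_i - kappa*x_i - beta*x_j)*dt
              + sigma*sqrt(dt)*eps_i)
```

with leak `kappa`, lateral inhibition `beta`, diffusion `sigma`,
zero-truncated evidence, synchronous updates from the previous state,
and the clamp applied after the full increment. A decision is made at
the first step where either accumulator reaches the threshold
`a(t) = max(0, a0 - c*t)`; observed RT adds a nondecision time `t0`.
Defaults: `kappa = beta = a0 = c = 4`, `sigma = 1`, `t0 = 0.3 s`,
`dt = 0.001 s`, horizon 10 s.

Design choices where the published description is underdetermined:

* **Collapse form is linear.** Only a scalar "collapse rate" is given;
  linear collapse with the stated defaults reaches zero at `a0/c`
  (1 s), guaranteeing termination. An exponential or Weibull collapse
  would need extra shape parameters that are nowhere stated. The
  functional form is isolated in `lca_params()` and easy to extend.
* **Tie-breaking.** If both accumulators cross on the same step
  (including the terminal instant where `a(t)` reaches 0), the larger
  evidence state wins; exact ties are resolved by a fair coin from the
  trial's random stream. With `c = 0` a trial can reach the horizon;
  it is then forced through the same tie rule and flagged `timed_out`.
* **Input mapping.** Sweeps set `I_correct = (s + d)/2`,
  `I_error = (s - d)/2` so the drift *difference* `d` (default 2) is
  fixed while the *sum* `s` tracks overall value; the replication grid
  is `s = 2..10` (the exact plotted x-values are not printed). The five
  named variants are `no_leak` (`kappa = 0`), `no_inhibition`
  (`beta = 0`), `no_collapse` (`a0 = 1, c = 0`), `cb_lca_1` (all
  defaults) and `cb_lca_2` (`a0 = 3, c = 2`).

Verification is two-route: a **deterministic ODE oracle**
(`deterministic_crossing_time()`, Euler step `dt/10`) checks the
small-noise limit against closed forms (`t* = a0/I` for the free
integrator, `t* = -log(1 - a0*kappa/I)/kappa` for the leaky one) and
against the stochastic simulator at `sigma = 1e-6`; the stochastic
suite checks choice symmetry at equal inputs, dt-halving stability, and
the qualitative pattern that gives the model its interest — with
collapsing bounds, accuracy *rises* and mean correct RT *falls* as the
input sum grows, while the fixed-bound variant loses accuracy.
Monotonicity is asserted up to twice the Monte-Carlo standard error of
each successive difference at 20,000 simulated trials per condition.
No exact first-passage solver is included; Monte Carlo plus the ODE
oracle is sufficient at these scales.

## The synthetic-data generator

`generate_glmm_study()` draws option values from a discrete-uniform law
(default integers 1–10, a typical rating scale), forces a configured
fraction of equal-value trials (default 0.1, implemented as the *total*
tie rate), and then simulates exactly the generative process the
fitting models assume: participant intercept and OV-slope deviations
drawn independently (no intercept–slope correlation — the fitted models
are agnostic to it), log-normal RTs, Bernoulli accuracy through the
logistic link. Because the accuracy model fits participant random OV
slopes, the generator also draws them (`sd_slope_ov_acc`, default
0.25); RV random slopes are omitted by default for identifiability at
desk scale. `generate_lca_study()` instead drives choices and RTs from
the CB-LCA with `I_i` proportional to the option values, which couples
RT, accuracy and OV mechanistically rather than statistically.

The default corpus (`corpus_spec()`) mirrors the 40-study composition
(5 abstract, 7 brightness, 7 numbers, 21 preference), with a true
accuracy OV effect of −0.25 log-odds/SD in brightness studies and 0
elsewhere — the qualitative pattern the reanalysis reports. Study sizes
default to 9 participants × 50 trials. That choice is a deliberate
**power calibration, made once at design time**: it places the corpus
in the same inferential regime as the published analysis (overall
accuracy z around −1.4, non-significant; brightness subgroup clearly
negative). One structural property is worth stating plainly: with the
brightness effect at −0.25 and all other true effects exactly zero, the
*true* corpus-mean effect is −0.044, not zero, so the "overall CI
includes 0" outcome is a power statement that holds in roughly 75–85%
of corpus replicates at any realistic study size — not a certainty.
The end-to-end test asks for it in at least 8 of 10 fixed-seed
replicates and is expected to sit near that boundary.

What the generator does **not** emulate: the original studies'
idiosyncratic designs (gambles, payoff schedules, dynamic stimuli),
unequal study sizes, non-normal RT contamination (fast guesses,
lapses), within-participant value drift, or between-study scatter of
the non-brightness true effects (the published between-study tau of
0.154 partly reflects real heterogeneity that the default corpus sets
to zero). Passing tests on synthetic corpora therefore certify the
*pipeline* — estimator correctness, calibration, recovery — not any
claim about new empirical data.

## Problem sizes and numerical notes

The test suite runs at desk scale by design: parameter-recovery blocks
use 40 × 300 trials (RT) and 20 × 150 (accuracy); type-I calibration
uses 20 null replicates; LCA acceptance sweeps use 20,000 simulations
per condition over input sums {2, 4, 6, 8, 10}; the end-to-end corpus
check uses 10 corpus seeds at the default composition. REML tolerance
is 1e-10; the Euler step is 0.001 s (oracle 0.0001 s); all stochastic
stages are seeded and bit-reproducible, with per-study and per-condition
sub-seeds derived from a single master seed.

## Known limitations

* BIC Bayes factors are conservative relative to full Bayesian model
  comparison with informative priors; labels near band boundaries
  should not be over-read.
* The moderator analysis is implemented but cannot be validated against
  the published result (the per-study flags are not printed).
* Per-study coefficients of the real 40 studies are not reproducible
  here (raw data external); only the pooled layer is.
* The LCA simulator is a plain Euler–Maruyama Monte-Carlo engine;
  first-passage densities, likelihood-based fitting, and non-linear
  collapse shapes are out of scope.
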
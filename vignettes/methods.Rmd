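---
title: "Methods: a two-stage learned policy for AF rhythm management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage learned policy for AF rhythm management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflearn)
```

## The decision problem

A patient with atrial fibrillation (AF) needs one of four rhythm-management
strategies: rate control (RAC), external cardioversion (EXC),
antiarrhythmic medication (AAM), or catheter ablation (AFA). `aflearn`
models this as a *single* decision with a *terminal* follow-up outcome —
a contextual bandit, not a sequential MDP: there is no successor state, no
discounting, and the learning target for the value model is the reward
itself. That framing is a deliberate design choice; extending to
multi-step treatment sequences is out of scope.

The context is the 8-feature clinical vector: age, AF duration (months),
resting heart rate, BMI (continuous), and heart-failure history,
left-atrial enlargement, hypertension, symptomatic status (binary).
Ejection fraction is *not* an input — the feature set follows the
enumerated 8-item list, and adding covariates silently would change the
model class. Missing features are a hard error, never imputed: a
decision-support tool must not guess clinical inputs.

### Feature encoding

`encode_features()` produces a frozen 9-vector: intercept (exactly 1),
the four continuous features z-scored with *training-cohort* statistics
(mean, sample n−1 SD), then the four 0/1 flags. Z-scoring keeps the
fixed-step SGD well behaved across features with wildly different units
(years vs beats/min); the n−1 convention is fixed and serialized with the
model so encodings are portable. AF duration is kept as continuous months
rather than binned — binning would invent cut-points the problem statement
does not supply.

## Stage one: supervised expert mimicry

The policy is a linear score per action, `s = W x` with a 4×9 weight
matrix. Two loss modes share one SGD update
`W ← W − α (p − e_a) x⊤`:

* `softmax_ce` (default): `p = softmax(s)`, cross-entropy against the
  chosen action. Proper for the model's advertised output — the
  *frequency* with which an expert would choose each strategy.
* `mse_onehot`: `p = s` raw, half squared error `½‖s − e_a‖²` against the
  one-hot label; the literal "linear regression per action" reading. At
  prediction time raw scores are clipped at zero and renormalized (uniform
  fallback when all clip), which preserves the argmax.

The ½ factor in the squared-error mode is what makes the two gradients
share the `(prediction − one-hot) ⊗ x` form exactly. Which loss the
original deployed system used is not determinable; both are provided and
neither is asserted as canonical.

Defaults: learning rate α = 0.1 (the supervised-stage constant), zero
initialization (both losses are convex in `W`, so the start point affects
only the path), per-record updates with per-epoch shuffles driven by an
explicit seed, no regularization (a ridge knob exists, default 0).
Reporting a single best action breaks ties by the fixed action order
RAC < EXC < AAM < AFA — deterministic, and visible in evaluation (an
untrained model "agrees" perfectly with an all-RAC cohort; the tests
document this artifact rather than hiding it).

A mimic is bounded by its labeler. With labels flipped to a uniform random
action at rate η, no classifier can agree with the noisy labeler above
`1 − 3η/4` in expectation. The suite checks this as an *upper bound* plus
monotone degradation — measured agreement sits clearly below the ceiling,
because constant-step SGD keeps bouncing around the optimum under label
noise rather than attaining the Bayes rule.

## Stage two: outcome-driven Q-learning

Follow-up provides three binary outcomes per treated patient; the scalar
reward is

`r = −2·stroke − hospitalization − symptomatic_recurrence ∈ [−4, 0]`,

with the weights exposed in `reward_spec()` but defaulting to exactly this
form (stroke, the most severe event, counts double). The value model is
linear per action, `Q(x, a) = V_a · x`, updated by the TD rule
`ΔV_a = α (r − Q(x, a)) x` with α = 0.01 — one order of magnitude below
the supervised stage, reflecting the preliminary nature of outcome
learning.

Two readings of "the error is propagated across each treatment" exist:
update only the taken action's row, or distribute the update over all
four. Only the first is compatible with off-policy value estimation (the
counterfactual actions' values must not be dragged toward an unrelated
reward), so the taken-row update is implemented and the alternative
rejected.

**Batching.** Updates are delivered in batches of 8 patients: every
per-example delta is computed at the *pre-batch* weights, the deltas are
averaged, and the aggregate applied once. Mean aggregation keeps the
effective step size independent of batch size and makes the result an
exact algebraic identity with a sequential fixed-weights oracle — and
therefore invariant to permutation within the batch, which the suite
checks exactly. A trailing partial batch is held in a pending buffer until
filled (updates are *only* delivered in full batches); `flush_partial =
TRUE` applies it with mean aggregation for end-of-stream use.

**Hand-off from stage one.** `q_from_sl()` copies the mimicry weights so
the initial greedy action matches the supervised argmax in every context
(the "scaffold" reading). Since rewards are non-positive, copied positive
scores are optimistic initial values and are pulled down by data.
Exploration during simulated deployment is ε-greedy (default ε = 0.1,
seeded); the choice of exploration scheme is an artifact decision.

## The blended recommender

`recommend()` returns `p = (1−β)·p_SL + β·softmax(Q/τ)` with
`β = min(1, n/N)`, where `n` counts outcome experiences consumed by
applied updates. The linear-in-experience schedule and its default
N = 500 are transparency choices — the transition is specified only as
"slow", and a linear ramp makes β auditable from the experience counter
alone. Temperature τ (default 1.0) maps unbounded Q-values into the same
frequency space as the mimicry output; as τ → 0⁺ the β = 1 recommendation
concentrates on the greedy action (checked at τ = 1e−6). A convex
combination of two distributions is always a distribution, so the output
frequencies are valid by construction and verified by property sweeps.
Display rounds percentages half-even to one decimal; machine-readable
JSON carries full precision.

## The synthetic world

No cohort for this problem is public, so the package *states* one:

* Covariates: age ~ N(68, 10) truncated to [35, 95]; AF duration ~
  LogNormal(ln 24, 0.8) months; resting HR ~ N(88, 15) on [40, 180]; BMI ~
  N(29, 5) on [16, 55]; Bernoulli flags with p(heart failure) = 0.3,
  p(LA enlargement) = 0.4, p(hypertension) = 0.6, p(symptomatic) = 0.55.
  These are invented, clinically plausible defaults for an AF-clinic
  population — not estimates of any real cohort, and the tests never
  depend on them beyond their own stated values.
* Expert: a ground-truth 4×9 score matrix W\* encoding textbook-leaning
  tendencies (older/asymptomatic/long-standing → RAC; recent-onset
  symptomatic → EXC; younger symptomatic → AFA). Labels are drawn from
  softmax(W\*x) by default, or its argmax in deterministic-expert mode —
  the mode used for the ≥ 95% recovery check, since a stochastic labeler
  caps achievable agreement well below 1.
* Outcomes: per-outcome logistic models over the encoded features plus an
  additive per-action effect (e.g. symptomatic recurrence is common under
  pure rate control in long-standing symptomatic disease, stroke is rare
  throughout).

The 100-record labelled initialization cohort
(`make_initialization_cohort()`) mirrors the chart-review bootstrap of the
supervised stage.

**What the simulator does not emulate:** missing data, measurement error,
longitudinal trajectories, treatment-selection confounding, site effects,
or any claim of epidemiologic realism. A green test on this world
establishes that the *estimators recover the stated generating process* —
not that the learned policy is clinically correct.

### Discrete oracle worlds

`discrete_world()` fixes K patient templates with tabulated Bernoulli
outcome rates per (context, action), so expected rewards — and hence the
optimal policy, exact policy values and exact regret — come in closed form
(by linearity of expectation, cross-checked against exhaustive enumeration
of the 8 outcome combinations to 1e−12). Two fixtures ship:

* `world_suboptimal_expert()`: clinically themed rates; the deterministic
  expert is optimal in three contexts but prescribes AAM in context 3
  (younger, symptomatic, long-standing AF) where ablation is better by
  0.49 reward units. Mimicry therefore has exact regret ≈ 0.12, and a
  trained greedy Q-policy must beat it — the policy-improvement claim is
  tested as exact regret dominance, not a Monte-Carlo comparison.
* `world_tabulated_bandit()`: the convergence oracle. Its four contexts
  use an orthogonal (Hadamard) ± layout of the continuous features with
  constant binaries, which minimizes and equalizes the encoded context
  norm, and its event rates are deliberately low (≤ ~7%). Both choices
  control the *noise floor* of the learner: with a fixed step size the
  weight iterate fluctuates around the optimum with standard deviation
  ≈ √(α‖x‖²σ²/2B), and with clinically sized event rates (reward variance
  σ² ≈ 0.5–1) that floor exceeds the 0.05 oracle tolerance no matter how
  long training runs. With this fixture the floor is ≈ 0.03, inside the
  tolerance at the suite's frozen seeds, while the optimal-vs-runner-up
  gap (≈ 0.06–0.08) stays far enough above the floor that greedy-policy
  recovery is essentially certain. The residual seed-to-seed spread means
  an unlucky draw can still graze the tolerance (in a 10-seed probe, 8/10
  were under 0.05 and the policy was recovered in 10/10); the tolerance
  itself was never adjusted.

## Evaluation

`policy_agreement()` is the fraction of records where the model argmax
matches the expert label. `policy_value()` is expected reward per
decision: exact (probability-weighted table lookups) in discrete worlds,
seeded Monte-Carlo with a reported standard error otherwise; the two
routes agree within 3 standard errors on the suite's checks. `regret()`
is the gap to the brute-force optimal policy — exactly ≥ 0 in discrete
mode. `learning_curve()` streams experiences under a behavior policy and
scores the model at experience-count checkpoints.

## Numerical and serialization choices

* Seeds: every stochastic routine takes an explicit seed and
  saves/restores the global RNG state, so library calls never perturb a
  caller's stream; (world, n, seed) determines a cohort bit-exactly.
* Truncated normals are sampled by inverse-CDF (exact, no rejection loop,
  deterministic draw count).
* Model JSON stores doubles with 17 significant digits — verified
  bit-exact on round trip (plain full-precision `toJSON` defaults are
  not). Files carry `format_version`, the frozen action and feature
  orders, and the scaler; loading refuses mismatched versions or orders.
* Ties everywhere break toward the lowest action index; degenerate
  inputs (empty cohorts, zero-variance features, unlabeled rows,
  out-of-range values) are structured-condition errors naming the field
  and row, not warnings.
* The CSV dialect is fixed: comma separator, required header, "." decimal.

## Known limitations

* Linear scores only — no interactions, no calibration layer, no neural
  extensions.
* The bandit framing cannot represent sequential strategy changes
  (e.g. failed cardioversion followed by ablation).
* Off-policy evaluation is simulator-based only; no doubly-robust or
  importance-sampling estimators, so nothing here evaluates a policy from
  observational data alone.
* The blend schedule is a stated artifact; the deployed system's actual
  transition rule, if any beyond "slow", is unknown.
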
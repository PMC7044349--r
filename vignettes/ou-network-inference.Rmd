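---
title: "Causal structure learning in OU networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal structure learning in OU networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ounet)
```

## The generative model

`ounet` models a small system of continuous variables (sliders bounded to
\[−100, 100\]) evolving in discrete 100 ms ticks. Each variable $i$ follows a
discrete-time Ornstein–Uhlenbeck process whose attractor is set by its causes:

$$\Delta v_i^t \sim \omega\Big[\sum_j \theta_{ji}\, v_j^t - v_i^t\Big] + \mathcal N(0, \sigma)$$

- $\omega \in (0, 1]$ is the per-tick mean-reversion rate (default 0.1): how
  sharply a variable is pulled toward its attractor.
- $\sigma \ge 0$ is the per-tick noise standard deviation in slider units
  (default 5). We read the Gaussian's second parameter as a standard
  deviation throughout, the conventional notation.
- $\theta_{ji}$ maps the value of cause $j$ onto the attractor of effect $i$.
  Multiple causes combine additively. A variable with no causes reverts
  toward 0. Edge labels are ternary: *regular* ($\theta > 0$), *inverse*
  ($\theta < 0$), *none* ($\theta = 0$); reference magnitude 1.

Values falling outside the bounds are clipped to the nearest bound, and
clipping is part of the generative model, not only of the display: the
inference side scores an observation sitting exactly on a bound with the tail
mass of the Gaussian beyond it, so generation and likelihood stay symmetric.

The update is fully synchronous: all drifts are computed from the complete
time-$t$ state, then noise, then clipping, then intervention overrides. An
intervened variable takes exactly its scheduled value — no noise, no
dynamics — mirroring a slider pinned by the mouse.

This family produces the qualitative dynamics one wants from a toy causal
universe: tracking of causes by effects, sign inversion for inverse links,
runaway positive feedback for reciprocal strengths above 1, damped feedback
below 1, and oscillation for reciprocal strengths of mismatched sign.

## Inference

### The normative learner

The hypothesis space for $n$ variables is every assignment of the three
labels to the $n(n-1)$ ordered pairs ($3^{n(n-1)}$ graphs; 729 for $n = 3$).
Enumeration is a ternary counter over the canonical pair order (lexicographic
by source then target), which fixes a reproducible graph indexing used for
serialisation and tie-breaking. (Note that the count is $3^{n(n-1)}$ in
general; $n = 3$ is the special case where this coincides with $3^{2n}$.)

The posterior of a graph multiplies, over variables and transitions, the
likelihood of each observed change under the graph's labels, marginalised
over parameter uncertainty with Gamma priors centred on the true values:

$$\theta \sim \Gamma(5\,\theta_{\text{ref}}, 5), \quad
  \omega \sim \Gamma(100\,\omega_{\text{ref}}, 100), \quad
  \sigma \sim \Gamma(100\,\sigma_{\text{ref}}, 100)$$

with $\theta_{\text{ref}} = 1$, $\omega_{\text{ref}} = 0.1$,
$\sigma_{\text{ref}} = 5$. Strength draws are negated for inverse labels and
pinned to an exact 0 for *none* (no draw is spent on absent edges). The
integrals are estimated by Monte Carlo with 1000 draws by default,
accumulated in log space with log-mean-exp (a 450-tick trajectory's
likelihood underflows otherwise).

Two estimator choices matter for cost and variance, and both leave the
estimand unchanged:

1. **Common random numbers.** One set of $(\omega, \sigma)$ draws and one
   positive magnitude draw per potential edge is shared by every graph.
2. **Parent-set factorisation.** Given the draws, a graph's likelihood
   factorises over variables, and a variable's factor depends only on the
   labels of its incoming edges. For $n = 3$ that is $3 \times 9 = 27$
   per-variable tables instead of 729 per-graph evaluations (~80× cheaper);
   the per-graph totals are then assembled by indexing. A unit test verifies
   exact equality with the naive per-graph evaluation, and a grid-quadrature
   oracle bounds the Monte-Carlo error at 0.05 log units on small problems.

### Interventions

Interventions are handled by graph surgery: a forced value carries
likelihood 1. The package applies the intervention flag at the *destination*
tick of a transition — the tick at which the value was forced — because that
is the observation the intervention explains; the source-tick convention is
available via `iota_timing = "source"`. The flag silences only the intervened
variable's own transition: an intervened cause still provides evidence about
its effects, which is exactly why holding a slider at an extreme is so
diagnostic.

### The Local Computations learner

The pairwise learner applies the same machinery to each ordered pair in
isolation: for pair $(j, i)$ it scores variable $i$'s transitions with $j$ as
the sole candidate cause under the three labels, and normalises. It never
holds a full graph, so it cannot explain away a mediated path: on chain data
$X \to Y \to Z$ it credits $X \to Z$ with high probability where the
normative learner correctly assigns it *none*. This divergence — verified as
a property test over 20 seeds — is the mechanism of interest for comparing
the two learners on behavioural data.

## Linear baselines

Six baselines assume a lag-1 linear model
$v_i^t \sim \mathcal N(\sum_j \beta_{ji} v_j^{t-1}, \sigma)$: Granger-style
variants include the self-predictor $\beta_{ii}$, time-lagged-correlation
variants exclude it; each runs on raw states, first differences, or
trinarized differences (signs of differences, with an exactly-zero
difference kept as a third category 0 — "trinarized" implies three values).
For difference representations the model is applied to the transformed
series, a difference is intervention-masked when either endpoint tick was
intervened, and no boundary-mass rule applies (differences are unbounded).

Priors mirror the OU ones: $\beta \sim \Gamma(5\hat\beta, 5)$ with inverse
edges negated, $\sigma \sim \Gamma(100\hat\sigma, 100)$. Two design choices
deserve note:

- **The self-predictor draw is shared across variables** within a Monte-Carlo
  sample, as $\omega$ is in the OU models. The OU dynamics rearrange to
  $v_i^{t+1} = (1-\omega)v_i^t + \omega\sum_j \theta_{ji} v_j^t + \varepsilon$,
  so $\beta_{ii} = 1-\omega$ is a property of the system, not of a variable.
  Practically, with per-variable independent draws a sample is useful only
  if *every* variable's draw lands in its narrow likelihood window
  (prior sd ≈ 0.4 against a likelihood sd of ≈ 0.01 per variable on a
  450-tick trial), which makes the estimator collapse; sharing restores MAP
  structure recovery to the ~0.9 level the correctly specified model should
  reach.
- **Reference magnitudes.** `default_linear_specs()` carries
  correspondence-motivated defaults ($\hat\beta_{ii} = 0.9$,
  $\hat\beta_{ji} = 0.1$, $\hat\sigma = 5$ for Granger/states, analogous
  scales elsewhere). `fit_reference_params()` implements the data-driven
  alternative — maximise the summed log posterior of the true graphs by
  multi-start coordinate search (successive golden-section sweeps on a log
  scale, shared draws across objective evaluations, deterministic given the
  seed). Be aware that this objective is discriminative: on strongly
  identified data it saturates (the true graph's posterior reaches 1 over a
  plateau), and even on weak data its optimum can sit at magnitudes well
  above the generating ones, because better sign discrimination outweighs a
  worse point fit. The fit is therefore a calibration device, not a
  consistent estimator of generating coefficients, and the package's tests
  assert its contract (determinism, finiteness, objective improvement)
  rather than parameter recovery.

## Choice model and comparison metrics

A posterior is turned into choice probabilities by a softmax on the log
posterior with one temperature $\tau$:
$p(g) \propto \exp(\log P(g \mid \text{data}) / \tau)$, i.e.
$P^{1/\tau}$ renormalised, so $\tau = 1$ recovers the Bayesian choice
probability, $\tau \to 0$ the argmax and $\tau \to \infty$ the uniform
distribution. Pairwise (edge-factored) models choose each pair independently
and the probability of a judged graph is the product over pairs. $\tau$ is
fitted globally per model by bounded 1-D maximum likelihood over
$[10^{-3}, 10^3]$ on a log scale.

Reported metrics: **accuracy** (fraction of trial × pair slots where the
model's MAP label matches the truth), **judge** (same, against the
responses), **BIC** $= -2\ell + k\ln n$ with $k = 1$ (the temperature) and
$n$ = number of judged trials (a trial's six responses are one selection; a
per-edge count is available via `bic_obs = "edges"`), and a per-participant
best-fit count with ties broken toward the simpler model (baseline first).
The baseline model scores every judgment uniformly over the graph space; it
has no most-probable graph, so its accuracy/judge entries are reported as
`NA`.

## What the synthetic agents emulate

The cohort generator stands in for behavioural data:

- **Interventions per trial**: shifted Poisson $1 + \text{Pois}(3.94)$,
  matching a mean of 4.94 with mode near 4; a coverage rule guarantees every
  variable is manipulated at least once (observed in over 99% of human
  trials), which nudges the realised mean slightly above 4.94.
- **Durations**: log-normal matched to mean 3.46 s, sd 3.0 s (only those two
  moments are known; log-normal is the standard positive-skew choice).
- **Values**: an episode ramps from rest to a held extreme (−100 or +100)
  and, with probability 0.5, sweeps on to the opposite extreme — the two
  modes of the observed intervention ranges — with ramp lengths sized so
  that ~71.2% of within-episode 100 ms windows repeat the previous value.
- **Placement**: uniformly random non-overlapping packing (one variable at a
  time), unspecified in the source behaviour and chosen for simplicity.
- **Judgments**: sampled from any model's softmax choice rule at a
  configurable $\tau$.

A deterministic diagnostic policy, `hold_extremes_schedule()`, holds each
variable in turn at +100 then −100 for 3 s with equal observation gaps; it
is the package's reference condition for structure-recovery benchmarks.

What the generator does *not* emulate: within-trial judgment revision,
perceptual/motor noise during drags, attention lapses, and any adaptivity of
the policy to what has been learned so far. Passing recovery and
model-recovery tests on this data therefore demonstrates the machinery, not
human-likeness: the synthetic cohorts are by construction exactly one of the
candidate models plus softmax noise.

## Numerical choices and degenerate inputs

- Boundary detection uses exact equality with the bounds; clipping writes
  exact bound values, so no tolerance is needed.
- Likelihood work is done on (transitions × draws) matrices per variable and
  parent configuration; all posteriors normalise via log-sum-exp.
- Fully intervened trajectories yield exactly uniform posteriors (every
  marginal is $\log 1 = 0$); a graph whose every draw underflows gets
  posterior 0 with a warning.
- MAP ties break toward the lowest canonical graph index (for edge
  posteriors: inverse < none < regular), making results reproducible.
- All randomness flows through explicit integer seeds; child seeds are
  derived by hashing a seed with a stream label, and the global RNG state is
  restored after every seeded call.

## Problem sizes used by the test-suite

The shipped checks run one 450-tick trial per battery network with 500–800
prior draws for structure recovery and representation ordering, 20 seeds of
160-tick chains for the mediation property, and two 6-participant ×
8-network cohorts at 300 draws for model recovery — sizes at which every
qualitative result above is stable under reseeding while the whole suite
stays inside a coffee break.

## Known limitations

- Enumeration is capped (default 60 000 graphs), so exact normative
  inference is practical for $n \le 3$; $n = 4$ needs the cap raised and
  patience, beyond that the hypothesis space explodes.
- Only linear attractor functions and zero-lag additive influence are
  implemented; distributed delays and nonlinear $f$ are out of scope.
- The Monte-Carlo marginal is a simple prior-sampling estimator; for very
  long trials or tight posteriors an annealed or adaptive scheme would be
  more efficient, but would break the common-random-numbers equivalence the
  factorisation relies on.
- The behavioural dataset reader ingests external JSON-lines datasets in the
  documented format, but fitting human data end-to-end (e.g. per-participant
  temperatures) is intentionally minimal.
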
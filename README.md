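# ounet

Causal structure learning in networks of Ornstein–Uhlenbeck processes.

People and algorithms alike face the problem of working out *what causes
what* in systems whose variables vary continuously and in real time —
hormone levels, market indices, coupled dials on a control panel. `ounet` is
an R toolkit for studying that problem at desk scale. It provides:

- a **generative model**: networks of coupled OU processes over bounded
  slider variables, simulated forward under arbitrary intervention
  schedules ("hold X at +100 for 3 s, release, …");
- two **OU-based learners** — a *normative* Bayesian posterior over every
  edge-labelled graph, and a *Local Computations* (LC) learner that scores
  each ordered pair in isolation;
- six **linear baselines**: {Granger causality, time-lagged correlation} ×
  {states, difference scores, trinarized difference scores};
- a **model-comparison layer**: softmax choice rule with fitted temperature
  τ, BIC, accuracy / judgment-agreement metrics, per-participant best-fit
  counts;
- **synthetic agents** that emulate a behavioural experiment end to end
  (a 23-network battery, play-like intervention policies, simulated
  judgments), so every analysis runs without any external data.

## The model

Each variable $i$ evolves in 100 ms ticks on a bounded scale $[-100, 100]$:

$$\Delta v_i^t \sim \omega\Big[\textstyle\sum_j \theta_{ji} v_j^t - v_i^t\Big] + \mathcal N(0,\sigma)$$

with mean-reversion rate $\omega$ (default 0.1), noise sd $\sigma$ (default
5) and signed strengths $\theta_{ji}$ (labels: regular $+1$, none $0$,
inverse $-1$). Values are clipped to the bounds; intervened variables take
exactly their scheduled value (graph surgery, likelihood 1). The normative
posterior over the $3^{n(n-1)}$ graphs (729 for three variables)
marginalises $\theta, \omega, \sigma$ over Gamma priors by Monte Carlo,
sped up ~80× by common random numbers and per-variable parent-set
factorisation; the LC learner applies the same machinery pairwise and
therefore cannot discount mediated links — the scientifically interesting
failure mode. See the methods vignette
(`vignettes/ou-network-inference.Rmd`) for the full account.

## Worked example

Simulate one experiment-like trial of the chain `X -> Y -> Z` under a
hold-each-variable-at-the-extremes policy, then invert it:

```r
library(ounet)

chain <- causal_graph(c("X", "Y", "Z"), c("X->Y" = 1, "Y->Z" = 1))
trial <- generate_trial(chain, params = ou_params(omega = 0.1, sigma = 5),
                        ticks = 450, seed = 42,
                        schedule = hold_extremes_schedule(450, c("X", "Y", "Z")))

post <- normative_posterior(trial, prior_spec(), n_samples = 1000, seed = 1)
post
#> graph_posterior over 729 graphs (1000 draws)
#>   MAP graph index 617 with probability 0.9487
map_graph(post)
#> causal_graph over {X, Y, Z}: 2 link(s)
#>   X->Y  +1 (regular)
#>   Y->Z  +1 (regular)
```

The normative learner recovers the chain, and its per-pair marginals assign
the mediated pair `X->Z` to *none* — it explains the X–Z covariation away
through Y:

```r
round(edge_marginals(post)[, ], 3)
#>      inverse  none regular
#> X->Y   0.000 0.000   1.000
#> X->Z   0.009 0.989   0.002
#> Y->X   0.000 1.000   0.000
#> Y->Z   0.000 0.000   1.000
#> Z->X   0.000 1.000   0.000
#> Z->Y   0.040 0.960   0.000
```

The pairwise LC learner, scoring each pair in isolation, is fooled by the
mediated path and marks `X->Z` as a regular link with probability 1:

```r
lc <- lc_posterior(trial, prior_spec(), n_samples = 1000, seed = 1)
round(unclass(lc)[, ], 3)
#>      inverse  none regular
#> X->Y   0.000 0.000       1
#> X->Z   0.000 0.000       1     <- mediated pair, overcredited
#> Y->X   0.030 0.970       0
#> Y->Z   0.000 0.000       1
#> Z->X   0.003 0.997       0
#> Z->Y   0.002 0.998       0
```

That contrast — identical data, identical priors, divergent verdicts on the
indirect link — is the package's central comparison. `compare_models()`
turns it quantitative: given a dataset of trials and ternary edge judgments
(simulated via `generate_cohort()`, or read from JSON-lines with
`read_dataset()`), it fits one softmax temperature per model and reports
accuracy, judgment agreement, BIC and per-participant best-fit counts.

A thin command-line surface wraps the same functions:

```sh
Rscript inst/cli/ounet.R simulate --graph chain.json --out trial.csv --seed 1
Rscript inst/cli/ounet.R infer --trajectory trial.csv --model normative --out post.tsv
Rscript inst/cli/ounet.R benchmark --model lc --out report.tsv
```

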
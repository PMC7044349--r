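Package: ounet
Title: Causal Structure Learning in Networks of Ornstein-Uhlenbeck Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates causal networks of coupled Ornstein-Uhlenbeck (OU)
    processes under user-specified interventions and infers the causal graph
    from interventional time series. Provides a fully Bayesian posterior over
    all edge-labelled graphs with Monte-Carlo marginalisation of parameter
    uncertainty, a Local Computations (pairwise) learner, and six lag-1
    linear baselines (Granger causality and time-lagged correlation on
    states, difference scores, and trinarized difference scores), together
    with a model-comparison layer (softmax choice rule, temperature fitting,
    BIC, accuracy and judgment-agreement metrics) and a synthetic-agent
    module that emulates interventional slider experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
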
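test_that("step likelihood handles interventions, interior and boundary cases", {
  # intervened transitions have likelihood 1
  expect_equal(step_loglik(c(40, 0), 77, target = 2, theta_col = c(1, 0),
                           omega = 0.1, sigma = 5, intervened = TRUE), 0)
  # density at the predicted mean: -log(sigma * sqrt(2 pi))
  expect_equal(step_loglik(c(40, 0), 4, target = 2, theta_col = c(1, 0),
                           omega = 0.1, sigma = 5),
               -log(5 * sqrt(2 * pi)), tolerance = 1e-10)
  expect_equal(-log(5 * sqrt(2 * pi)), -2.528377, tolerance = 1e-6)
  # value clipped at the top scores the upper tail mass: predicted mean 101
  prev <- c(90, 0); theta <- c(0, 0)
  # choose prev so that m = prev_i + omega * (0 - prev_i) = 101 directly:
  ll <- step_loglik(c(0, 0) + c(101 / 0.9, 0), 100, target = 1,
                    theta_col = c(0, 0), omega = 0.1, sigma = 5)
  expect_equal(ll, pnorm(0.2, log.p = TRUE), tolerance = 1e-10)
  expect_equal(exp(ll), 0.5793, tolerance = 1e-4)
  expect_error(step_loglik(c(0, 0), 101, target = 1, theta_col = c(0, 0),
                           omega = 0.1, sigma = 5), "pre-clipped")
})

test_that("trajectory log likelihood sums step contributions and obeys masks", {
  g <- single_edge_graph(1)
  th <- graph_to_theta(g)
  tr <- toy_trajectory()
  # single transition of a single free variable equals step_loglik
  tr2 <- trajectory(tr$values[1:2, ], cbind(X = c(1, 1), Y = c(0, 0)))
  expect_equal(trajectory_loglik(tr2, th, 0.1, 5),
               step_loglik(tr$values[1, ], tr$values[2, "Y"], target = 2,
                           theta_col = th[, "Y"], omega = 0.1, sigma = 5))
  # fully intervened variable contributes nothing: perturbing its values at
  # intervened ticks leaves the total unchanged
  vals <- tr$values; vals[2, "X"] <- -50
  tr3 <- trajectory(vals, tr$mask)
  expect_equal(
    trajectory_loglik(tr3, th, 0.1, 5) -
      trajectory_loglik(tr, th, 0.1, 5),
    # only the transition *out of* the altered state changes (X feeds Y),
    # so compare variable X's own masked contribution: recompute directly
    (step_loglik(tr3$values[2, ], tr3$values[3, "Y"], 2, th[, "Y"], 0.1, 5) -
     step_loglik(tr$values[2, ], tr$values[3, "Y"], 2, th[, "Y"], 0.1, 5)) +
    (step_loglik(tr3$values[2, ], tr3$values[3, "X"], 1, th[, "X"], 0.1, 5) -
     step_loglik(tr$values[2, ], tr$values[3, "X"], 1, th[, "X"], 0.1, 5)))
  # a trajectory whose every tick is intervened scores exactly 0
  allm <- trajectory(tr$values, matrix(1, 4, 2))
  expect_equal(trajectory_loglik(allm, th, 0.1, 5), 0)
})

test_that("the generating graph outscores single-edge perturbations of it", {
  g <- chain_graph()
  sch <- hold_extremes_schedule(200, vars3, seed = 1)
  tr <- generate_trial(g, ou_params(omega = 0.1, sigma = 1), ticks = 200,
                       seed = 9, schedule = sch)
  th_true <- graph_to_theta(g)
  ll_true <- trajectory_loglik(tr, th_true, 0.1, 1)
  for (pair in names(g)) {
    for (lab in setdiff(c(-1, 0, 1), g[pair])) {
      g2 <- g; g2[pair] <- as.integer(lab)
      expect_lt(trajectory_loglik(tr, graph_to_theta(g2), 0.1, 1), ll_true)
    }
  }
})

test_that("prior draws have the specified Gamma moments and are seed-stable", {
  d <- sample_priors(prior_spec(), vars3, n_samples = 20000, seed = 1)
  expect_equal(mean(d$theta), 1, tolerance = 0.03)
  expect_equal(mean(d$omega), 0.1, tolerance = 0.01)
  expect_equal(mean(d$sigma), 5, tolerance = 0.02)
  expect_equal(dim(d$theta), c(6L, 20000L))
  d2 <- sample_priors(prior_spec(), vars3, n_samples = 20000, seed = 1)
  expect_identical(d, d2)
  expect_error(prior_spec(theta_mean = 0), "theta_mean")
})

test_that("factorised marginal likelihood equals a naive per-graph evaluation", {
  g <- chain_graph()
  tr <- generate_trial(g, ticks = 25, seed = 21,
                       schedule = hold_extremes_schedule(25, vars3, hold_ticks = 3))
  draws <- sample_priors(prior_spec(), vars3, n_samples = 40, seed = 2)
  for (graph in list(g, causal_graph(3),
                     causal_graph(3, c("Y->X" = -1, "Z->Y" = 1)))) {
    naive <- local({
      per <- vapply(seq_len(draws$n_samples), function(s) {
        th <- graph_to_theta_draws(graph, draws, s)
        oracle_traj_loglik(tr, th, draws$omega[s], draws$sigma[s])
      }, 0)
      max(per) + log(mean(exp(per - max(per))))
    })
    expect_equal(marginal_loglik(tr, graph, draws = draws), naive,
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo marginal likelihood matches grid quadrature on toy cases", {
  tr <- toy_trajectory()
  spec <- prior_spec()
  nq <- 60
  oms <- quad_nodes(10, 100, nq); sgs <- quad_nodes(500, 100, nq)
  ths <- quad_nodes(5, 5, nq)

  # empty graph: 2-D integral over (omega, sigma)
  g0 <- causal_graph(c("X", "Y"))
  vals <- as.vector(outer(oms, sgs, Vectorize(function(om, sg)
    oracle_traj_loglik(tr, matrix(0, 2, 2), om, sg))))
  quad0 <- max(vals) + log(mean(exp(vals - max(vals))))
  mc0 <- marginal_loglik(tr, g0, spec, n_samples = 1e5, seed = 7)
  expect_equal(mc0, quad0, tolerance = 0.05)

  # single regular edge: 3-D integral over (theta, omega, sigma)
  g1 <- single_edge_graph(1)
  vals1 <- numeric(0)
  for (th in ths) {
    theta <- matrix(c(0, 0, th, 0), 2, 2) # X -> Y
    vals1 <- c(vals1, as.vector(outer(oms, sgs, Vectorize(function(om, sg)
      oracle_traj_loglik(tr, theta, om, sg)))))
  }
  quad1 <- max(vals1) + log(mean(exp(vals1 - max(vals1))))
  mc1 <- marginal_loglik(tr, g1, spec, n_samples = 1e5, seed = 7)
  expect_equal(mc1, quad1, tolerance = 0.05)

  # MAP graph on a strongly identified trajectory is seed-invariant even
  # though the marginal estimates differ across seeds
  g <- single_edge_graph(1)
  sch <- intervention_schedule(list(list(variable = "X", start = 0, end = 50,
                                         values = 100)))
  trs <- simulate_ou(g, ou_params(), sch, ticks = 100, seed = 5)
  p1 <- normative_posterior(trs, spec, n_samples = 1000, seed = 1)
  p2 <- normative_posterior(trs, spec, n_samples = 1000, seed = 2)
  expect_false(identical(p1$log_marginal, p2$log_marginal))
  expect_identical(map_graph(p1), map_graph(p2))
})

test_that("altering an intervened value leaves its silenced transition untouched", {
  # the destination-tick flag makes an intervened observation free of charge
  expect_equal(step_loglik(c(0, 0), 100, target = 1, theta_col = c(0, 0),
                           omega = 0.1, sigma = 5, intervened = TRUE), 0)
  # a value forced at the final tick feeds no later transition, so changing
  # it must leave every likelihood untouched
  g <- single_edge_graph(1)
  vals <- cbind(X = c(10, 8, 7, 100), Y = c(0, 1, 2, 3))
  mask <- cbind(X = c(0L, 0L, 0L, 1L), Y = rep(0L, 4))
  tr_a <- trajectory(vals, mask)
  vals[4, "X"] <- -100
  tr_b <- trajectory(vals, mask)
  th <- graph_to_theta(g)
  expect_equal(trajectory_loglik(tr_a, th, 0.1, 5),
               trajectory_loglik(tr_b, th, 0.1, 5))
  draws <- sample_priors(prior_spec(), c("X", "Y"), 50, seed = 3)
  expect_equal(marginal_loglik(tr_a, g, draws = draws),
               marginal_loglik(tr_b, g, draws = draws))
  # with source-tick timing the silenced transition is the one leaving the
  # intervened tick instead
  expect_equal(trajectory_loglik(tr_a, th, 0.1, 5, iota_timing = "source"),
               trajectory_loglik(tr_b, th, 0.1, 5, iota_timing = "source") -
                 step_loglik(tr_b$values[3, ], tr_b$values[4, "X"], 1,
                             th[, "X"], 0.1, 5) +
                 step_loglik(tr_a$values[3, ], tr_a$values[4, "X"], 1,
                             th[, "X"], 0.1, 5))
})

test_that("posterior over graphs normalises, recovers a chain, and is uniform when uninformed", {
  # fully intervened trajectory: exactly uniform posterior
  tr <- trajectory(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                          dimnames = list(NULL, c("X", "Y"))),
                   mask = matrix(1L, 3, 2))
  post <- normative_posterior(tr, n_samples = 30, seed = 1)
  expect_equal(post$posterior, rep(1 / 9, 9))
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)

  # a single noisy transition is weak evidence: near-uniform posterior
  tr2 <- trajectory(matrix(c(2, -1, 1, 3), 2, 2,
                           dimnames = list(NULL, c("X", "Y"))))
  post2 <- normative_posterior(tr2, n_samples = 2000, seed = 2)
  expect_lt(max(post2$posterior) / min(post2$posterior), 10)

  # long interventional chain trial: MAP is the exact chain, including the
  # mediated pair labelled none
  g <- chain_graph()
  tr3 <- generate_trial(g, seed = 31,
                        schedule = hold_extremes_schedule(450, vars3, seed = 3))
  post3 <- normative_posterior(tr3, n_samples = 500, seed = 3)
  m <- map_graph(post3)
  expect_identical(as.integer(m), as.integer(g))
  expect_equal(unname(m["X->Z"]), 0L)
  expect_equal(sum(post3$posterior), 1, tolerance = 1e-9)
})

test_that("the pairwise learner concentrates correctly and ignores third variables", {
  g <- single_edge_graph(1)
  sch <- intervention_schedule(list(
    list(variable = "X", start = 0, end = 40, values = 100),
    list(variable = "X", start = 60, end = 100, values = -100),
    list(variable = "Y", start = 120, end = 160, values = 100),
    list(variable = "Y", start = 180, end = 220, values = -100)))
  tr <- simulate_ou(g, ou_params(), sch, ticks = 260, seed = 8)
  ep <- lc_posterior(tr, n_samples = 500, seed = 1)
  expect_gt(ep["X->Y", "regular"], 0.95)
  expect_gt(ep["Y->X", "none"], 0.95)
  expect_equal(rowSums(unclass(ep)), setNames(rep(1, 2), rownames(ep)),
               tolerance = 1e-9)
  # fully intervened: uniform over the three labels for every pair
  trm <- trajectory(tr$values[1:5, ], matrix(1L, 5, 2))
  epm <- lc_posterior(trm, n_samples = 30, seed = 1)
  expect_equal(matrix(as.numeric(epm), 2, 3), matrix(1 / 3, 2, 3))
})

test_that("edge marginals conserve probability and collapse point masses", {
  gs <- enumerate_graphs(c("X", "Y"))
  # point mass on one graph
  k <- 7
  post <- structure(list(variables = c("X", "Y"),
                         log_marginal = ifelse(seq_len(9) == k, 0, -1e9),
                         log_posterior = ifelse(seq_len(9) == k, 0, -1e9),
                         posterior = as.numeric(seq_len(9) == k),
                         n_samples = 1),
                    class = "graph_posterior")
  em <- edge_marginals(post)
  expect_equal(unname(em[cbind(1:2, as.integer(gs[[k]]) + 2L)]), c(1, 1))
  # uniform posterior: every pair uniform
  postu <- structure(list(variables = c("X", "Y"),
                          log_marginal = rep(0, 9),
                          log_posterior = rep(log(1 / 9), 9),
                          posterior = rep(1 / 9, 9), n_samples = 1),
                     class = "graph_posterior")
  expect_equal(matrix(as.numeric(edge_marginals(postu)), 2, 3),
               matrix(1 / 3, 2, 3))
  # arbitrary posterior: triples sum to 1
  set.seed(1)
  p <- runif(9); p <- p / sum(p)
  posta <- postu; posta$posterior <- p
  expect_equal(unname(rowSums(unclass(edge_marginals(posta)))), c(1, 1))
})

test_that("MAP extraction breaks ties toward the lowest canonical index", {
  post <- structure(list(variables = c("X", "Y"),
                         log_marginal = rep(0, 9),
                         log_posterior = c(log(0.3), rep(log(0.05), 4),
                                           log(0.3), rep(log(0.1), 3)),
                         posterior = c(0.3, rep(0.05, 4), 0.3, rep(0.1, 3)),
                         n_samples = 1),
                    class = "graph_posterior")
  expect_equal(graph_index(map_graph(post)), 1L)
  ep2 <- structure(matrix(c(0.2, 0.5, 0.3, 1 / 3, 1 / 3, 1 / 3), 2, 3,
                          byrow = TRUE,
                          dimnames = list(c("X->Y", "Y->X"),
                                          c("inverse", "none", "regular"))),
                   variables = c("X", "Y"), class = "edge_posterior")
  m <- map_graph(ep2)
  expect_equal(unname(m["X->Y"]), 0L)   # argmax none
  expect_equal(unname(m["Y->X"]), -1L)  # exact tie -> inverse (lowest)
})
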
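test_that("representation transforms difference, trinarize, and propagate masks", {
  tr <- trajectory(cbind(X = c(0, 4, 3), Y = c(1, 1, 1)),
                   mask = cbind(X = c(0, 1, 0), Y = c(0, 0, 0)))
  expect_identical(transform_trajectory(tr, "states"), tr)
  d <- transform_trajectory(tr, "differences")
  expect_equal(unname(d$values[, "X"]), c(4, -1))
  expect_equal(nrow(d$values), 2)
  # a difference is masked when either endpoint was intervened
  expect_equal(unname(d$mask[, "X"]), c(1, 1))
  expect_equal(unname(d$mask[, "Y"]), c(0, 0))
  tr2 <- trajectory(cbind(X = c(0, 3.2, 2.7, 2.7)))
  tz <- transform_trajectory(tr2, "trinarized")
  expect_equal(unname(tz$values[, 1]), c(1, -1, 0))
  expect_error(transform_trajectory(trajectory(cbind(X = c(1, 2))),
                                    "differences"), "3 ticks")
})

test_that("linear step likelihood honours self term, masks and truncation", {
  # no parents, no self: mean 0, density at mode
  expect_equal(linear_step_loglik(c(0, 0), 0, target = 1, beta_col = c(0, 0),
                                  include_self = FALSE, sigma_lin = 5),
               -log(5 * sqrt(2 * pi)), tolerance = 1e-12)
  # persistence predictor puts the mode at the previous value
  expect_equal(linear_step_loglik(c(10, 0), 10, target = 1,
                                  beta_col = c(1, 0), include_self = TRUE,
                                  sigma_lin = 5),
               -log(5 * sqrt(2 * pi)), tolerance = 1e-12)
  # the same beta_col without the self flag predicts 0 instead
  expect_lt(linear_step_loglik(c(10, 0), 10, target = 1, beta_col = c(1, 0),
                               include_self = FALSE, sigma_lin = 5),
            -log(5 * sqrt(2 * pi)))
  # masked destination scores log 1
  expect_equal(linear_step_loglik(c(10, 0), 99, target = 1,
                                  beta_col = c(1, 0), include_self = TRUE,
                                  sigma_lin = 5, intervened = TRUE), 0)
  # truncation applies only with finite bounds
  ll <- linear_step_loglik(c(120, 0) * 0 + c(110, 0), 100, target = 1,
                           beta_col = c(1, 0), include_self = TRUE,
                           sigma_lin = 5, bounds = c(-100, 100))
  expect_equal(ll, pnorm(100, 110, 5, lower.tail = FALSE, log.p = TRUE))
})

test_that("linear marginal likelihood matches grid quadrature on a toy case", {
  tr <- toy_trajectory()
  g1 <- single_edge_graph(1)
  lsp <- linear_prior_spec(0.1, 0.9, 5)
  mc <- linear_marginal_loglik(tr, g1, lsp, "granger", "states",
                               n_samples = 2e5, seed = 7)
  # oracle: X depends on (beta_self, sigma); Y on (beta_edge, beta_self, sigma);
  # the shared self draw couples the variables, so integrate jointly
  nq <- 48
  bE <- quad_nodes(5 * 0.1, 5, nq)
  bS <- quad_nodes(5 * 0.9, 5, nq)
  sg <- quad_nodes(100 * 5, 100, nq)
  v <- tr$values
  vals <- numeric(0)
  for (bs in bS) {
    llX <- dnorm(v[3, 1], bs * v[2, 1], sg, log = TRUE) +
           dnorm(v[4, 1], bs * v[3, 1], sg, log = TRUE)
    for (be in bE) {
      llY <- colSums(vapply(seq_along(sg), function(si)
        dnorm(v[2:4, 2], be * v[1:3, 1] + bs * v[1:3, 2], sg[si], log = TRUE),
        numeric(3)))
      vals <- c(vals, llX + llY)
    }
  }
  quad <- max(vals) + log(mean(exp(vals - max(vals))))
  expect_equal(mc, quad, tolerance = 0.05)
})

test_that("a fully masked trajectory has marginal likelihood 1 under any baseline", {
  tr <- trajectory(cbind(X = c(1, 2, 3), Y = c(0, 1, 0)),
                   mask = matrix(1L, 3, 2))
  lsp <- linear_prior_spec(0.5, 0.5, 5)
  expect_equal(linear_marginal_loglik(tr, causal_graph(c("X", "Y")), lsp,
                                      "lagcorr", "states", 50, seed = 1), 0)
  expect_equal(linear_marginal_loglik(tr, causal_graph(c("X", "Y")), lsp,
                                      "granger", "states", 50, seed = 1), 0)
})

test_that("trinarization destroys magnitude information", {
  # same sign pattern, wildly different magnitudes -> identical likelihoods
  base <- cbind(X = c(0, 5, -3, 4, -2), Y = c(0, 2, -1, 3, -4))
  big <- base * 19.7
  tra <- trajectory(base); trb <- trajectory(big)
  lsp <- linear_prior_spec(0.5, 0.5, 1)
  g <- single_edge_graph(1)
  for (variant in c("granger", "lagcorr")) {
    a <- linear_marginal_loglik(tra, g, lsp, variant, "trinarized", 100, seed = 2)
    b <- linear_marginal_loglik(trb, g, lsp, variant, "trinarized", 100, seed = 2)
    expect_identical(a, b)
  }
})

test_that("linear graph posteriors normalise and use the uniform graph prior", {
  g <- chain_graph()
  tr <- generate_trial(g, seed = 5,
                       schedule = hold_extremes_schedule(450, vars3, seed = 5))
  post <- linear_posterior(tr, linear_prior_spec(0.1, 0.9, 5),
                           "granger", "states", n_samples = 300, seed = 1)
  expect_length(post$posterior, 729)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  # fully masked data: exactly uniform (prior only)
  trm <- trajectory(tr$values[1:4, ], matrix(1L, 4, 3))
  postm <- linear_posterior(trm, linear_prior_spec(0.1, 0.9, 5),
                            "lagcorr", "states", n_samples = 30, seed = 1)
  expect_equal(postm$posterior, rep(1 / 729, 729))
})

test_that("reference-parameter fitting is deterministic, finite and improves its objective", {
  g <- chain_graph()
  ds <- lapply(1:2, function(s) {
    list(graph = g,
         trajectory = generate_trial(g, ticks = 80, seed = 40 + s,
                                     schedule = hold_extremes_schedule(
                                       80, vars3, hold_ticks = 10)))
  })
  fp1 <- fit_reference_params(ds, "granger", "states", n_samples = 60,
                              seed = 2, sweeps = 1)
  fp2 <- fit_reference_params(ds, "granger", "states", n_samples = 60,
                              seed = 2, sweeps = 1)
  expect_identical(fp1[c("beta_edge", "beta_self", "sigma", "objective")],
                   fp2[c("beta_edge", "beta_self", "sigma", "objective")])
  expect_true(is.finite(fp1$beta_edge) && is.finite(fp1$sigma) &&
              is.finite(fp1$objective))
  expect_gt(fp1$beta_edge, 0)
  expect_gt(fp1$sigma, 0)
  # single-trial degenerate dataset still returns finite values
  fp3 <- fit_reference_params(ds[1], "lagcorr", "trinarized", n_samples = 40,
                              seed = 3, sweeps = 1)
  expect_true(is.finite(fp3$beta_edge) && is.finite(fp3$sigma))
  expect_true(is.na(fp3$beta_self))
})
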
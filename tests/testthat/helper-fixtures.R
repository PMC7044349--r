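# Shared fixture builders. Everything is generated in code at test time.

vars3 <- c("X", "Y", "Z")

chain_graph <- function() causal_graph(vars3, c("X->Y" = 1, "Y->Z" = 1))

single_edge_graph <- function(label = 1) {
  causal_graph(c("X", "Y"), c("X->Y" = label))
}

# a short, strongly intervened two-variable trajectory for oracle tests
toy_trajectory <- function() {
  trajectory(cbind(X = c(40, 35, 30, 28), Y = c(0, 5, 8, 12)),
             mask = cbind(X = c(1, 1, 0, 0), Y = c(0, 0, 0, 0)))
}

# one hold-at-extremes trial per fixture network, seeded
battery_trials <- function(nets, ticks = 450, seed_base = 1000) {
  lapply(seq_along(nets), function(k) {
    sch <- hold_extremes_schedule(ticks, vars3, seed = k)
    generate_trial(nets[[k]], seed = seed_base + k, schedule = sch)
  })
}

# independent quadrature oracle over the Gamma priors: equal-mass nodes per
# dimension, likelihood evaluated with plain dnorm/pnorm sums (no package
# likelihood code).
quad_nodes <- function(shape, rate, n) {
  qgamma(seq(1 / (2 * n), 1 - 1 / (2 * n), length.out = n), shape, rate)
}

# strength matrix implied by one Monte-Carlo draw and a graph's labels
graph_to_theta_draws <- function(graph, draws, s) {
  vars <- attr(graph, "variables")
  n <- length(vars)
  theta <- matrix(0, n, n, dimnames = list(vars, vars))
  for (p in names(graph)) {
    if (graph[p] != 0) {
      jt <- strsplit(p, "->", fixed = TRUE)[[1]]
      theta[jt[1], jt[2]] <- as.integer(graph[p]) * draws$theta[p, s]
    }
  }
  theta
}

oracle_traj_loglik <- function(traj, theta, omega, sigma) {
  v <- traj$values; m <- traj$mask
  lo <- traj$bounds[1]; hi <- traj$bounds[2]
  tot <- 0
  for (t in seq_len(nrow(v) - 1L)) {
    for (i in seq_len(ncol(v))) {
      if (m[t + 1L, i] == 1) next
      mu <- v[t, i] + omega * (sum(theta[, i] * v[t, ]) - v[t, i])
      x <- v[t + 1L, i]
      tot <- tot + if (x >= hi) {
        pnorm(hi, mu, sigma, lower.tail = FALSE, log.p = TRUE)
      } else if (x <= lo) {
        pnorm(lo, mu, sigma, log.p = TRUE)
      } else dnorm(x, mu, sigma, log = TRUE)
    }
  }
  tot
}
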
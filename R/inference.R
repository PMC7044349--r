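#' Log likelihood of a single observed transition
#'
#' One variable, one tick-to-tick transition. If the variable is intervened on
#' at the destination tick its observed value is forced by the intervention
#' (graph surgery), so the likelihood is 1 (log 0). Otherwise the next value
#' is Gaussian around the drifted mean
#' `m = prev_i + omega * (sum_j theta_col[j] * prev_state[j] - prev_i)`;
#' an observation lying exactly on a bound is scored with the tail mass of
#' the Gaussian beyond that bound (the generative model clips to bounds).
#'
#' @param prev_state Numeric vector: full state at the source tick.
#' @param next_value Observed value of the target variable at the next tick
#'   (must lie within the closed bounds; clip before calling).
#' @param target Index of the target variable i within `prev_state`.
#' @param theta_col Strengths into the target, aligned with `prev_state`
#'   (entry at `target` must be 0; no self loops).
#' @param omega,sigma OU parameters; `sigma > 0`.
#' @param intervened Was the target intervened on at the destination tick?
#' @param bounds Slider limits `(lo, hi)`.
#' @return Log likelihood (scalar).
#' @examples
#' # density at the predicted mean of a regular X -> Y link
#' step_loglik(c(40, 0), 4, target = 2, theta_col = c(1, 0),
#'             omega = 0.1, sigma = 5)
#' @export
step_loglik <- function(prev_state, next_value, target, theta_col,
                        omega, sigma, intervened = FALSE,
                        bounds = c(-100, 100)) {
  if (intervened) return(0)
  if (sigma <= 0) stop_contract("sigma must be > 0 for likelihood evaluation")
  if (length(theta_col) != length(prev_state)) {
    stop_contract("theta_col must align with prev_state")
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (next_value < lo || next_value > hi) {
    stop_contract("next_value outside bounds; inputs must be pre-clipped")
  }
  next_value <- unname(next_value)
  prev_i <- unname(prev_state[target])
  m <- prev_i + omega * (sum(theta_col * prev_state) - prev_i)
  if (next_value == hi) {
    pnorm(hi, mean = m, sd = sigma, lower.tail = FALSE, log.p = TRUE)
  } else if (next_value == lo) {
    pnorm(lo, mean = m, sd = sigma, lower.tail = TRUE, log.p = TRUE)
  } else {
    dnorm(next_value, mean = m, sd = sigma, log = TRUE)
  }
}

#' Log likelihood of a whole trajectory at fixed parameters
#'
#' Sum of [step_loglik()] over every variable and every transition
#' `t -> t + 1`. By default a transition of variable i is silenced (likelihood
#' 1) when i is intervention-masked at the destination tick `t + 1`, i.e. when
#' its value there was forced rather than generated.
#'
#' @param traj An `ou_trajectory`.
#' @param theta Square strength matrix.
#' @param omega,sigma OU parameters.
#' @param iota_timing Which tick's intervention flag silences a transition:
#'   `"destination"` (default) or `"source"`.
#' @return Scalar log likelihood.
#' @export
trajectory_loglik <- function(traj, theta, omega, sigma,
                              iota_timing = c("destination", "source")) {
  iota_timing <- match.arg(iota_timing)
  v <- traj$values
  T_ <- nrow(v)
  if (T_ < 2L) stop_contract("need at least 2 ticks")
  lo <- traj$bounds[1]; hi <- traj$bounds[2]
  prev <- v[-T_, , drop = FALSE]
  nxt <- v[-1L, , drop = FALSE]
  flag <- if (iota_timing == "destination") traj$mask[-1L, , drop = FALSE]
          else traj$mask[-T_, , drop = FALSE]
  att <- prev %*% theta # attractor term, (T-1) x n
  total <- 0
  for (i in seq_len(ncol(v))) {
    keep <- flag[, i] == 0
    if (!any(keep)) next
    m <- prev[keep, i] + omega * (att[keep, i] - prev[keep, i])
    x <- nxt[keep, i]
    ll <- numeric(length(x))
    up <- x == hi; dn <- x == lo; mid <- !up & !dn
    ll[mid] <- dnorm(x[mid], m[mid], sigma, log = TRUE)
    if (any(up)) ll[up] <- pnorm(hi, m[up], sigma, lower.tail = FALSE, log.p = TRUE)
    if (any(dn)) ll[dn] <- pnorm(lo, m[dn], sigma, lower.tail = TRUE, log.p = TRUE)
    total <- total + sum(ll)
  }
  total
}

# ---- Monte-Carlo marginalisation engine ------------------------------------
#
# The marginal likelihood of a graph factorises over variables given the
# parameter draws: each variable's contribution depends only on the labels of
# its incoming edges (its "parent configuration"). With n variables there are
# 3^(n-1) configurations per variable (9 for n = 3) instead of 3^(n(n-1))
# full graphs (729), and one common set of draws is shared across all graphs
# (common random numbers).

# Per-variable context: everything that does not depend on the configuration.
variable_context <- function(traj, i, draws, iota_timing = "destination") {
  v <- traj$values
  T_ <- nrow(v)
  lo <- traj$bounds[1]; hi <- traj$bounds[2]
  flagm <- if (iota_timing == "destination") traj$mask[-1L, , drop = FALSE]
           else traj$mask[-T_, , drop = FALSE]
  keep <- flagm[, i] == 0
  prev <- v[-T_, , drop = FALSE][keep, , drop = FALSE]
  x <- v[-1L, i][keep]
  S <- draws$n_samples
  rows <- nrow(prev)
  others <- setdiff(seq_len(ncol(v)), i)
  vars <- traj$variables
  list(
    i = i, others = others, rows = rows, S = S, lo = lo, hi = hi,
    prev_others = prev[, others, drop = FALSE],
    base_mean = if (rows) outer(prev[, i], 1 - draws$omega) else NULL, # rows x S
    omega_row = draws$omega,
    sig_mat = if (rows) matrix(draws$sigma, rows, S, byrow = TRUE) else NULL,
    x = x, up = x == hi, dn = x == lo,
    theta_rows = draws$theta[paste0(vars[others], "->", vars[i]), , drop = FALSE]
  )
}

# Per-draw log likelihood (length S) of variable i's transitions under one
# parent-label configuration.
config_loglik <- function(ctx, labels) {
  S <- ctx$S
  if (ctx$rows == 0L) return(numeric(S))
  if (all(labels == 0)) {
    M <- ctx$base_mean
  } else {
    Th <- ctx$theta_rows * labels # recycles labels down rows (one per parent)
    A <- ctx$prev_others %*% Th # rows x S
    M <- ctx$base_mean + sweep(A, 2L, ctx$omega_row, "*")
  }
  Z <- (ctx$x - M) / ctx$sig_mat
  LL <- -log(ctx$sig_mat) - 0.9189385332046727 - 0.5 * Z * Z
  if (any(ctx$up)) {
    LL[ctx$up, ] <- pnorm(ctx$hi, M[ctx$up, , drop = FALSE],
                          ctx$sig_mat[ctx$up, , drop = FALSE],
                          lower.tail = FALSE, log.p = TRUE)
  }
  if (any(ctx$dn)) {
    LL[ctx$dn, ] <- pnorm(ctx$lo, M[ctx$dn, , drop = FALSE],
                          ctx$sig_mat[ctx$dn, , drop = FALSE],
                          lower.tail = TRUE, log.p = TRUE)
  }
  colSums(LL)
}

# All 3^(n-1) parent configurations of each variable: returns per variable a
# (n_config x S) matrix of per-draw log likelihoods plus the label matrix.
all_config_logliks <- function(traj, draws, iota_timing = "destination") {
  n <- length(traj$variables)
  p <- n - 1L
  cfg_labels <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), p))[, p:1, drop = FALSE])
  # row k of cfg_labels = ternary digits of (k-1), first parent most significant
  lapply(seq_len(n), function(i) {
    ctx <- variable_context(traj, i, draws, iota_timing)
    ll <- t(vapply(seq_len(nrow(cfg_labels)),
                   function(k) config_loglik(ctx, cfg_labels[k, ]),
                   numeric(draws$n_samples)))
    list(labels = cfg_labels, ll = ll)
  })
}

# index of a parent-label configuration in the expand.grid order above
config_index <- function(labels) {
  p <- length(labels)
  as.integer(sum((labels + 1L) * 3^(p - seq_len(p)))) + 1L
}

#' Monte-Carlo log marginal likelihood of one graph
#'
#' Estimates the marginal likelihood of the trajectory under a graph by
#' averaging the likelihood over parameter draws from the priors (log-mean-exp
#' in log space): strength magnitudes are drawn per edge and signed by the
#' edge labels (negated for inverse, pinned to 0 for none), and `omega`,
#' `sigma` are drawn once per sample.
#'
#' @param traj An `ou_trajectory`.
#' @param graph A `causal_graph` over the trajectory's variables.
#' @param spec A [prior_spec()].
#' @param n_samples Number of Monte-Carlo draws. Default 1000.
#' @param seed Integer seed for the draws.
#' @param draws Optional precomputed [sample_priors()] object (overrides
#'   `spec`, `n_samples`, `seed`).
#' @param iota_timing See [trajectory_loglik()].
#' @return Scalar log marginal likelihood estimate; `-Inf` (with a warning)
#'   if every draw underflows.
#' @export
marginal_loglik <- function(traj, graph, spec = prior_spec(),
                            n_samples = 1000, seed = NULL, draws = NULL,
                            iota_timing = c("destination", "source")) {
  iota_timing <- match.arg(iota_timing)
  if (is.null(draws)) {
    draws <- sample_priors(spec, traj$variables, n_samples, seed)
  }
  n <- length(traj$variables)
  per_draw <- numeric(draws$n_samples)
  for (i in seq_len(n)) {
    ctx <- variable_context(traj, i, draws, iota_timing)
    per_draw <- per_draw + config_loglik(ctx, parents_of(graph, i))
  }
  out <- logmeanexp(per_draw)
  if (!is.finite(out)) warning("all Monte-Carlo draws underflowed; returning -Inf")
  out
}

#' Posterior over all graphs (normative model)
#'
#' The full Bayesian learner: a uniform prior over every edge-labelled graph,
#' each scored by its Monte-Carlo marginal likelihood with parameter
#' uncertainty integrated out, then normalised. Per-variable parent-set
#' factorisation and common random numbers make the cost linear in
#' `n * 3^(n-1)` configurations rather than `3^(n(n-1))` graphs.
#'
#' @inheritParams marginal_loglik
#' @return Object of class `graph_posterior`: list with `log_marginal`,
#'   `log_posterior`, `posterior` (all length `3^(n(n-1))`, aligned with
#'   [enumerate_graphs()] order), `variables`, `n_samples`.
#' @examples
#' g <- causal_graph(c("X", "Y"), c("X->Y" = 1))
#' sch <- intervention_schedule(list(list(variable = "X", start = 0,
#'                                        end = 40, values = 100)))
#' tr <- simulate_ou(g, ou_params(), sch, ticks = 80, seed = 2)
#' post <- normative_posterior(tr, n_samples = 300, seed = 1)
#' map_graph(post)
#' @export
normative_posterior <- function(traj, spec = prior_spec(), n_samples = 1000,
                                seed = NULL, draws = NULL,
                                iota_timing = c("destination", "source")) {
  iota_timing <- match.arg(iota_timing)
  if (is.null(draws)) {
    draws <- sample_priors(spec, traj$variables, n_samples, seed)
  }
  tabs <- all_config_logliks(traj, draws, iota_timing)
  new_graph_posterior_from_tabs(traj$variables, tabs, draws$n_samples)
}

new_graph_posterior_from_tabs <- function(variables, tabs, n_samples) {
  labs <- enumerate_graph_labels(variables)
  pairs <- colnames(labs)
  n <- length(variables)
  total <- matrix(0, nrow(labs), n_samples)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    cols <- match(paste0(variables[others], "->", variables[i]), pairs)
    p <- length(others)
    cfg_idx <- rep(1L, nrow(labs))
    for (k in seq_len(p)) {
      cfg_idx <- cfg_idx + (labs[, cols[k]] + 1L) * 3^(p - k)
    }
    total <- total + tabs[[i]]$ll[cfg_idx, , drop = FALSE]
  }
  log_marg <- row_logmeanexp(total)
  lz <- logsumexp(log_marg)
  log_post <- log_marg - lz
  structure(list(variables = variables, log_marginal = log_marg,
                 log_posterior = log_post, posterior = exp(log_post),
                 n_samples = n_samples),
            class = "graph_posterior")
}

#' @export
print.graph_posterior <- function(x, ...) {
  k <- which.max(x$posterior)
  cat("graph_posterior over ", length(x$posterior), " graphs (",
      x$n_samples, " draws)\n  MAP graph index ", k, " with probability ",
      signif(x$posterior[k], 4), "\n", sep = "")
  invisible(x)
}

#' Per-edge posterior of the Local Computations model
#'
#' The pairwise learner: for each ordered pair (j, i) it scores the three
#' label hypotheses (inverse / none / regular) using only variable i's
#' transitions with j as the sole candidate cause, marginalising `theta`,
#' `omega`, `sigma` over the same priors as the normative model, and
#' normalises over the three labels. All other variables are ignored for that
#' pair, so mediated relationships are not discounted.
#'
#' @inheritParams marginal_loglik
#' @return Object of class `edge_posterior`: a `n(n-1) x 3` matrix of
#'   probabilities with columns `inverse`, `none`, `regular` and rows in
#'   canonical pair order; attribute `log_marginal` holds the unnormalised
#'   per-label log marginals.
#' @export
lc_posterior <- function(traj, spec = prior_spec(), n_samples = 1000,
                         seed = NULL, draws = NULL,
                         iota_timing = c("destination", "source")) {
  iota_timing <- match.arg(iota_timing)
  if (is.null(draws)) {
    draws <- sample_priors(spec, traj$variables, n_samples, seed)
  }
  vars <- traj$variables
  n <- length(vars)
  pairs <- graph_pairs(vars)
  lm <- matrix(NA_real_, length(pairs), 3,
               dimnames = list(pairs, c("inverse", "none", "regular")))
  ctxs <- lapply(seq_len(n), variable_context, traj = traj, draws = draws,
                 iota_timing = iota_timing)
  for (pk in seq_along(pairs)) {
    pm <- pair_matrix(vars)
    j <- pm[pk, 1L]; i <- pm[pk, 2L]
    ctx <- ctxs[[i]]
    jpos <- match(j, ctx$others)
    for (l in c(-1L, 0L, 1L)) {
      labels <- integer(n - 1L)
      labels[jpos] <- l
      lm[pk, l + 2L] <- logmeanexp(config_loglik(ctx, labels))
    }
  }
  post <- t(apply(lm, 1L, function(r) exp(r - logsumexp(r))))
  dimnames(post) <- dimnames(lm)
  new_edge_posterior(post, vars, log_marginal = lm)
}

new_edge_posterior <- function(prob, variables, log_marginal = NULL) {
  structure(prob, variables = variables, log_marginal = log_marginal,
            class = "edge_posterior")
}

#' @export
print.edge_posterior <- function(x, ...) {
  cat("edge_posterior over ", nrow(x), " ordered pairs\n", sep = "")
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

#' Per-edge marginals of a graph posterior
#'
#' Sums graph probabilities by each ordered pair's label, collapsing the
#' joint posterior into independent three-way distributions per pair.
#'
#' @param post A `graph_posterior`.
#' @return An `edge_posterior`.
#' @export
edge_marginals <- function(post) {
  stopifnot(inherits(post, "graph_posterior"))
  labs <- enumerate_graph_labels(post$variables)
  pairs <- colnames(labs)
  out <- matrix(NA_real_, length(pairs), 3,
                dimnames = list(pairs, c("inverse", "none", "regular")))
  for (p in seq_along(pairs)) {
    for (l in c(-1L, 0L, 1L)) {
      out[p, l + 2L] <- sum(post$posterior[labs[, p] == l])
    }
  }
  new_edge_posterior(out, post$variables)
}

#' Most probable graph under a posterior
#'
#' For a `graph_posterior`, the argmax graph; for an `edge_posterior`, the
#' per-pair argmax labels assembled into a graph. Exact ties are broken
#' toward the lowest canonical index (for edges: inverse < none < regular).
#'
#' @param post A `graph_posterior` or `edge_posterior`.
#' @return A `causal_graph`.
#' @export
map_graph <- function(post) UseMethod("map_graph")

#' @export
map_graph.graph_posterior <- function(post) {
  labs <- enumerate_graph_labels(post$variables)
  k <- which.max(post$posterior) # first maximum = lowest index
  causal_graph(post$variables, setNames(labs[k, ], colnames(labs)))
}

#' @export
map_graph.edge_posterior <- function(post) {
  vars <- attr(post, "variables")
  lab <- apply(unclass(post), 1L, which.max) - 2L
  causal_graph(vars, setNames(as.integer(lab), rownames(post)))
}
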
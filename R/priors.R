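#' Prior specification for OU-network inference
#'
#' Gamma priors over the parameters a learner is uncertain about, centred on
#' reference values with fixed concentration: strength magnitude
#' `theta ~ Gamma(shape = 5 * theta_mean, rate = 5)`, reversion rate
#' `omega ~ Gamma(shape = 100 * omega_mean, rate = 100)` and noise sd
#' `sigma ~ Gamma(shape = 100 * sigma_mean, rate = 100)`. Sampled strengths
#' are negated for inverse connections and pinned to exactly 0 for
#' non-connections.
#'
#' @param theta_mean Prior mean of the strength magnitude. Default 1.
#' @param omega_mean Prior mean of the reversion rate. Default 0.1.
#' @param sigma_mean Prior mean of the noise sd. Default 5.
#' @return Object of class `prior_spec` holding shape/rate pairs.
#' @export
prior_spec <- function(theta_mean = 1, omega_mean = 0.1, sigma_mean = 5) {
  stopifnot(theta_mean > 0, omega_mean > 0, sigma_mean > 0)
  structure(list(
    theta_shape = 5 * theta_mean, theta_rate = 5,
    omega_shape = 100 * omega_mean, omega_rate = 100,
    sigma_shape = 100 * sigma_mean, sigma_rate = 100
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "prior_spec:\n  theta ~ Gamma(%.3g, %.3g) (mean %.3g)\n",
    "  omega ~ Gamma(%.3g, %.3g) (mean %.3g)\n",
    "  sigma ~ Gamma(%.3g, %.3g) (mean %.3g)\n"),
    x$theta_shape, x$theta_rate, x$theta_shape / x$theta_rate,
    x$omega_shape, x$omega_rate, x$omega_shape / x$omega_rate,
    x$sigma_shape, x$sigma_rate, x$sigma_shape / x$sigma_rate))
  invisible(x)
}

#' Draw Monte-Carlo parameter samples from the priors
#'
#' One positive strength magnitude is drawn per potential edge and per sample
#' (common random numbers: the same draws are reused for every graph that
#' includes the edge), alongside shared `omega` and `sigma` draws.
#'
#' @param spec A [prior_spec()].
#' @param variables Variable names (determines the set of potential edges).
#' @param n_samples Number of draws. Default 1000.
#' @param seed Integer seed; the draws are deterministic given the seed.
#' @return Object of class `prior_draws`: list with `theta` (pairs x
#'   n_samples matrix of positive magnitudes, rownames = pair keys), `omega`
#'   and `sigma` (length n_samples), `n_samples`.
#' @export
sample_priors <- function(spec, variables, n_samples = 1000, seed = NULL) {
  if (!inherits(spec, "prior_spec")) stop_contract("spec must be a prior_spec")
  if (n_samples < 1L) stop_contract("n_samples must be >= 1")
  variables <- default_variables(variables)
  pairs <- graph_pairs(variables)
  with_seed(seed, {
    theta <- matrix(rgamma(length(pairs) * n_samples,
                           shape = spec$theta_shape, rate = spec$theta_rate),
                    nrow = length(pairs), dimnames = list(pairs, NULL))
    omega <- rgamma(n_samples, spec$omega_shape, spec$omega_rate)
    sigma <- rgamma(n_samples, spec$sigma_shape, spec$sigma_rate)
    structure(list(theta = theta, omega = omega, sigma = sigma,
                   n_samples = as.integer(n_samples), variables = variables),
              class = "prior_draws")
  })
}
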
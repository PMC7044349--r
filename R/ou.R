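#' Parameters of an Ornstein-Uhlenbeck network
#'
#' Per-tick dynamics of every variable: the expected change pulls the value
#' toward an attractor with rate `omega`, plus Gaussian noise with standard
#' deviation `sigma`; values are truncated to `bounds` after each update. The
#' attractor of a variable is the strength-weighted sum of its causes'
#' current values (0 for a variable with no causes).
#'
#' @param omega Mean-reversion rate per tick, in (0, 1]. Default 0.1.
#' @param sigma Per-tick noise standard deviation, slider units. Default 5.
#' @param dt_ms Tick duration in milliseconds (informational). Default 100.
#' @param bounds Length-2 numeric `(lo, hi)` slider limits. Default
#'   `c(-100, 100)`.
#' @return Object of class `ou_params`.
#' @export
ou_params <- function(omega = 0.1, sigma = 5, dt_ms = 100, bounds = c(-100, 100)) {
  stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(omega = omega, sigma = sigma, dt_ms = dt_ms,
                 bounds = as.numeric(bounds)),
            class = "ou_params")
}

#' Expected per-tick change of every variable
#'
#' Deterministic part of the network dynamics:
#' `drift_i = omega * (sum_j theta[j,i] * state_j - state_i)`. Variables with
#' no parents revert toward 0.
#'
#' @param state Numeric vector of current values (slider units).
#' @param theta Square strength matrix (`theta[j, i]` = strength of j on i).
#' @param omega Mean-reversion rate per tick.
#' @return Numeric vector of expected changes.
#' @examples
#' th <- matrix(0, 3, 3); th[1, 2] <- 1
#' ou_drift(c(40, 0, 0), th, 0.1) # c(-4, 4, 0)
#' @export
ou_drift <- function(state, theta, omega) {
  if (length(state) != nrow(theta) || nrow(theta) != ncol(theta)) {
    stop_contract("state length must match the (square) theta dimension")
  }
  omega * (drop(state %*% theta) - state)
}

#' Advance an OU network by one tick
#'
#' Fully synchronous update: all drifts are computed from the time-t state,
#' Gaussian noise is added, values are clipped to bounds, and finally any
#' intervened variable is overridden with its scheduled value (no noise, no
#' dynamics for intervened variables). Noise is drawn from the current RNG
#' stream; seed at the [simulate_ou()] level.
#'
#' @param state Numeric vector of current values, within bounds.
#' @param theta Square strength matrix.
#' @param params An [ou_params()] object.
#' @param interventions Named numeric vector (variable -> held value) for this
#'   tick, or `NULL`. Values outside bounds are clipped with a warning.
#' @param variables Variable names positionally matching `state` (needed only
#'   when `interventions` is named).
#' @return Numeric vector: the state at the next tick.
#' @export
ou_step <- function(state, theta, params, interventions = NULL,
                    variables = names(state)) {
  lo <- params$bounds[1]; hi <- params$bounds[2]
  if (any(state < lo | state > hi)) stop_contract("state outside bounds")
  nxt <- state + ou_drift(state, theta, params$omega)
  if (params$sigma > 0) nxt <- nxt + rnorm(length(state), 0, params$sigma)
  nxt <- pmin(pmax(nxt, lo), hi)
  if (length(interventions)) {
    idx <- match(names(interventions), variables)
    if (anyNA(idx)) stop_contract("intervention on unknown variable")
    v <- as.numeric(interventions)
    if (any(v < lo | v > hi)) {
      warning("scheduled intervention value outside bounds; clipped")
      v <- pmin(pmax(v, lo), hi)
    }
    nxt[idx] <- v
  }
  nxt
}

#' Simulate an OU network under an intervention schedule
#'
#' Unrolls the network for `ticks` steps from `init` (tick 0). A variable that
#' the schedule holds at some tick takes exactly the scheduled value at that
#' tick; all other variables follow the stochastic dynamics. Identical seeds
#' give identical trajectories.
#'
#' @param graph A `causal_graph`, or a square strength matrix used directly.
#' @param params An [ou_params()] object.
#' @param schedule An [intervention_schedule()] or `NULL` for a pure
#'   observation trial.
#' @param ticks Number of ticks T (rows). Default 450 (45 s at 100 ms ticks).
#' @param init Initial state at tick 0; a scalar is recycled. Default 0.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param magnitude Strength magnitude for converting a `causal_graph`
#'   (ignored when `graph` is already a matrix). Default 1.
#' @return An `ou_trajectory`: list with `values` (T x n matrix), `mask`
#'   (T x n 0/1 intervention indicators), `variables`, `bounds`.
#' @examples
#' g <- causal_graph(c("X", "Y"), c("X->Y" = 1))
#' tr <- simulate_ou(g, ou_params(), ticks = 50, seed = 1)
#' @export
simulate_ou <- function(graph, params = ou_params(), schedule = NULL,
                        ticks = 450, init = 0, seed = NULL, magnitude = 1) {
  if (inherits(graph, "causal_graph")) {
    variables <- graph_variables(graph)
    theta <- graph_to_theta(graph, magnitude)
  } else {
    theta <- as.matrix(graph)
    variables <- rownames(theta) %||% paste0("V", seq_len(nrow(theta)))
  }
  n <- length(variables)
  if (ticks < 2L) stop_contract("need at least 2 ticks")
  held <- schedule_values(schedule, ticks, variables) # T x n, NA = free
  mask <- !is.na(held)
  lo <- params$bounds[1]; hi <- params$bounds[2]
  if (any(held < lo | held > hi, na.rm = TRUE)) {
    warning("scheduled intervention value outside bounds; clipped")
    held <- pmin(pmax(held, lo), hi)
  }
  values <- matrix(NA_real_, ticks, n, dimnames = list(NULL, variables))
  state <- pmin(pmax(rep_len(as.numeric(init), n), lo), hi)
  state[mask[1L, ]] <- held[1L, mask[1L, ]]
  values[1L, ] <- state
  with_seed(seed, {
    for (t in seq_len(ticks - 1L)) {
      nxt <- state + ou_drift(state, theta, params$omega)
      if (params$sigma > 0) nxt <- nxt + rnorm(n, 0, params$sigma)
      nxt <- pmin(pmax(nxt, lo), hi)
      forced <- mask[t + 1L, ]
      nxt[forced] <- held[t + 1L, forced]
      values[t + 1L, ] <- nxt
      state <- nxt
    }
  })
  new_trajectory(values, mask * 1L, variables, params$bounds)
}

new_trajectory <- function(values, mask, variables, bounds) {
  dimnames(values) <- list(NULL, variables)
  dimnames(mask) <- list(NULL, variables)
  structure(list(values = values, mask = mask, variables = variables,
                 bounds = as.numeric(bounds)),
            class = "ou_trajectory")
}

#' Assemble a trajectory object from matrices
#'
#' @param values T x n numeric matrix of variable values, within `bounds`.
#' @param mask T x n 0/1 matrix of intervention indicators (default all 0).
#' @param variables Variable names (default from `values` column names).
#' @param bounds Slider limits the values must respect.
#' @return An `ou_trajectory`.
#' @export
trajectory <- function(values, mask = NULL, variables = colnames(values),
                       bounds = c(-100, 100)) {
  values <- as.matrix(values)
  if (is.null(variables)) variables <- paste0("V", seq_len(ncol(values)))
  if (nrow(values) < 2L) stop_contract("a trajectory needs at least 2 ticks")
  if (is.null(mask)) mask <- matrix(0L, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values))) stop_contract("mask/values shape mismatch")
  if (!all(mask %in% c(0, 1))) stop_contract("mask entries must be 0/1")
  if (any(values < bounds[1] | values > bounds[2])) {
    stop_contract("values outside bounds [", bounds[1], ", ", bounds[2], "]")
  }
  new_trajectory(values, mask, variables, bounds)
}

#' @export
print.ou_trajectory <- function(x, ...) {
  cat("ou_trajectory: ", nrow(x$values), " ticks x ", length(x$variables),
      " variables (", paste(x$variables, collapse = ", "), "); ",
      sum(x$mask), " intervened cell(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.ou_trajectory <- function(x) dim(x$values)
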
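#' Softmax choice probabilities from a posterior
#'
#' Converts a model posterior into choice probabilities with a single
#' temperature parameter: `p(g) propto exp(log P(g | data) / tau)`
#' (equivalently `posterior^(1/tau)` renormalised). `tau = 1` recovers the
#' posterior, `tau -> 0` the argmax, `tau -> Inf` the uniform distribution.
#' Graphs with posterior probability 0 keep probability 0 at any finite
#' `tau`. For an `edge_posterior` the rule applies independently per pair.
#'
#' @param post A `graph_posterior` or `edge_posterior`.
#' @param tau Softmax temperature, > 0.
#' @param log Return log probabilities? Default `FALSE`.
#' @return Numeric vector over graphs, or a pairs x 3 matrix of per-label
#'   probabilities.
#' @export
choice_distribution <- function(post, tau, log = FALSE) {
  stopifnot(tau > 0)
  UseMethod("choice_distribution")
}

#' @export
choice_distribution.graph_posterior <- function(post, tau, log = FALSE) {
  lp <- post$log_posterior / tau
  lp <- lp - logsumexp(lp)
  if (log) lp else exp(lp)
}

#' @export
choice_distribution.edge_posterior <- function(post, tau, log = FALSE) {
  lp <- base::log(unclass(post)) / tau
  lp <- lp - apply(lp, 1L, logsumexp)
  if (log) lp else exp(lp)
}

#' Log likelihood of judged structures under a model's choice rule
#'
#' Sums, over trials, the log choice probability of the judged graph. For
#' edge-factored posteriors the judged graph's probability is the product of
#' its per-pair label choice probabilities. A `"baseline"` entry scores the
#' judged graph uniformly over the hypothesis space, independent of `tau`.
#'
#' @param posteriors List (one per trial) of `graph_posterior`,
#'   `edge_posterior`, or the string `"baseline"`.
#' @param judgments List (one per trial) of judged structures
#'   (`causal_graph` or named label vectors over the canonical pairs).
#' @param tau Softmax temperature.
#' @return Total log likelihood; `-Inf` (with a warning) when a judged graph
#'   has choice probability 0.
#' @export
judgment_loglik <- function(posteriors, judgments, tau) {
  stopifnot(length(posteriors) == length(judgments))
  total <- 0
  for (k in seq_along(posteriors)) {
    total <- total + single_judgment_loglik(posteriors[[k]], judgments[[k]], tau)
  }
  if (!is.finite(total)) warning("a judged graph has choice probability 0")
  total
}

single_judgment_loglik <- function(post, judgment, tau) {
  if (identical(post, "baseline")) {
    m <- length(judgment)
    return(-m * base::log(3))
  }
  if (inherits(post, "graph_posterior")) {
    lp <- choice_distribution(post, tau, log = TRUE)
    return(lp[graph_index(judgment)])
  }
  if (inherits(post, "edge_posterior")) {
    lp <- choice_distribution(post, tau, log = TRUE)
    lab <- as.integer(judgment)[match(rownames(post), names(judgment))]
    return(sum(lp[cbind(seq_len(nrow(post)), lab + 2L)]))
  }
  stop_contract("unsupported posterior type")
}

#' Maximum-likelihood softmax temperature
#'
#' 1-D bounded maximisation of [judgment_loglik()] over `tau` on a log scale.
#'
#' @inheritParams judgment_loglik
#' @param interval Search bounds for `tau`. Default `c(1e-3, 1e3)`.
#' @return List with `tau` and `loglik`. A boundary solution (flat or
#'   degenerate likelihood) triggers a warning.
#' @export
fit_tau <- function(posteriors, judgments, interval = c(1e-3, 1e3)) {
  if (!length(posteriors)) stop_contract("non-empty dataset required")
  f <- function(ltau) suppressWarnings(judgment_loglik(posteriors, judgments, exp(ltau)))
  opt <- optimize(f, interval = base::log(interval), maximum = TRUE, tol = 1e-4)
  tau <- exp(opt$maximum)
  if (tau / interval[1] < 1.05 || interval[2] / tau < 1.05) {
    warning("fitted tau lies at the search boundary")
  }
  list(tau = tau, loglik = opt$objective)
}

#' Bayesian Information Criterion
#'
#' @param loglik Maximised log likelihood.
#' @param k Number of free parameters.
#' @param n_obs Number of observations.
#' @return `-2 * loglik + k * log(n_obs)`.
#' @export
bic <- function(loglik, k, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * loglik + k * base::log(n_obs)
}

#' Proportion of true edge labels identified by MAP graphs
#'
#' Fraction of (trial, ordered pair) slots where the model's MAP label equals
#' the true label.
#'
#' @param map_graphs,true_graphs Aligned lists of `causal_graph`s.
#' @return Proportion in \[0, 1\].
#' @export
accuracy_metric <- function(map_graphs, true_graphs) {
  stopifnot(length(map_graphs) == length(true_graphs))
  hits <- mapply(function(m, g) as.integer(m) == as.integer(g),
                 map_graphs, true_graphs)
  mean(unlist(hits))
}

#' Agreement between MAP graphs and judged structures
#'
#' Fraction of slots where the judged label equals the model's MAP label.
#'
#' @param map_graphs List of MAP `causal_graph`s.
#' @param judgments Aligned list of judged structures.
#' @return Proportion in \[0, 1\].
#' @export
judge_metric <- function(map_graphs, judgments) {
  accuracy_metric(map_graphs, judgments)
}

#' Participants best fit by each model
#'
#' For each participant the model with the highest judgment log likelihood
#' (each model evaluated at its own globally fitted `tau`) receives one
#' count. Exact ties go to the model earliest in `tie_order` (put simpler /
#' baseline models first).
#'
#' @param ll Matrix of per-participant log likelihoods (rows = participants,
#'   columns = models, named).
#' @param tie_order Preference order for ties; default the column order.
#' @return Named integer vector of counts summing to `nrow(ll)`.
#' @export
best_fit_table <- function(ll, tie_order = colnames(ll)) {
  stopifnot(!is.null(colnames(ll)), all(tie_order %in% colnames(ll)))
  pref <- match(colnames(ll), tie_order)
  counts <- setNames(integer(ncol(ll)), colnames(ll))
  for (r in seq_len(nrow(ll))) {
    mx <- max(ll[r, ])
    cand <- which(ll[r, ] == mx)
    win <- cand[which.min(pref[cand])]
    counts[win] <- counts[win] + 1L
  }
  counts
}

ounet_models <- c("normative", "lc",
                  "granger-states", "granger-diff", "granger-trinary",
                  "lagcorr-states", "lagcorr-diff", "lagcorr-trinary",
                  "baseline")

parse_model_name <- function(model) {
  if (model %in% c("normative", "lc", "baseline")) return(list(kind = model))
  parts <- strsplit(model, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("granger", "lagcorr") ||
      !parts[2] %in% c("states", "diff", "trinary")) {
    stop_contract("unknown model name: ", model)
  }
  list(kind = "linear", variant = parts[1],
       rep = c(states = "states", diff = "differences",
               trinary = "trinarized")[[parts[2]]])
}

# posterior of one model for one trial (tabs/draws not shared across models
# here; compare_models() shares the OU tables between normative and lc).
trial_posterior <- function(model, traj, spec, linear_specs, n_samples, seed) {
  pm <- parse_model_name(model)
  switch(pm$kind,
    normative = normative_posterior(traj, spec, n_samples, seed),
    lc = lc_posterior(traj, spec, n_samples, seed),
    baseline = "baseline",
    linear = {
      lspec <- linear_specs[[model]]
      if (is.null(lspec)) stop_contract("no linear_prior_spec supplied for ", model)
      linear_posterior(traj, lspec, pm$variant, pm$rep, n_samples, seed)
    })
}

#' Fit and score a set of models on a judgment dataset
#'
#' The full comparison pipeline: compute each model's posterior per trial,
#' fit one softmax temperature per model across all trials by maximum
#' likelihood, and report per-model accuracy (MAP vs. truth), judgment
#' agreement (MAP vs. responses), BIC of all judgments, and the number of
#' participants best fit. The normative and Local Computations models share
#' per-trial likelihood tables and Monte-Carlo draws. The baseline model
#' scores every judgment uniformly (its accuracy and agreement are reported
#' as `NA`: it has no most-probable graph).
#'
#' @param dataset List of trial records: each a list with `participant`,
#'   `graph` (true `causal_graph`), `trajectory`, `judgment`.
#' @param models Character vector of model names among
#'   `r paste(ounet_models, collapse = ", ")`.
#' @param spec [prior_spec()] for the OU models.
#' @param linear_specs Named list of [linear_prior_spec()], one per linear
#'   model requested (names matching the model strings).
#' @param n_samples Monte-Carlo draws per trial posterior.
#' @param seed Master seed; per-trial draw seeds are derived from it.
#' @param bic_obs Count judged `"trials"` (default; one multinomial selection
#'   per trial) or `"edges"` as BIC observations.
#' @return List with `table` (data frame: model, tau, loglik, bic, accuracy,
#'   judge, n_best), `ll_participant` (participants x models matrix), `taus`,
#'   and `posteriors` (per model, per trial).
#' @export
compare_models <- function(dataset, models = c("normative", "lc", "baseline"),
                           spec = prior_spec(), linear_specs = list(),
                           n_samples = 1000, seed = 1,
                           bic_obs = c("trials", "edges")) {
  bic_obs <- match.arg(bic_obs)
  stopifnot(length(dataset) > 0, all(models %in% ounet_models))
  truths <- lapply(dataset, `[[`, "graph")
  judgments <- lapply(dataset, `[[`, "judgment")
  participants <- vapply(dataset, function(r) as.character(r$participant), "")
  n_trials <- length(dataset)

  posteriors <- setNames(vector("list", length(models)), models)
  for (m in models) posteriors[[m]] <- vector("list", n_trials)

  share_ou <- all(c("normative", "lc") %in% models)
  for (k in seq_len(n_trials)) {
    traj <- dataset[[k]]$trajectory
    tseed <- derive_seed(seed, "trial", k)
    if (share_ou) {
      draws <- sample_priors(spec, traj$variables, n_samples, tseed)
      posteriors[["normative"]][[k]] <-
        normative_posterior(traj, draws = draws)
      posteriors[["lc"]][[k]] <- lc_posterior(traj, draws = draws)
    }
    for (m in setdiff(models, if (share_ou) c("normative", "lc") else character())) {
      posteriors[[m]][[k]] <-
        trial_posterior(m, traj, spec, linear_specs, n_samples, tseed)
    }
  }

  n_pairs <- length(graph_pairs(dataset[[1]]$trajectory$variables))
  n_obs <- if (bic_obs == "trials") n_trials else n_trials * n_pairs
  rows <- list()
  ll_p <- matrix(NA_real_, length(unique(participants)), length(models),
                 dimnames = list(unique(participants), models))
  taus <- setNames(numeric(length(models)), models)
  for (m in models) {
    pm <- posteriors[[m]]
    if (m == "baseline") {
      tau <- NA_real_
      ll <- judgment_loglik(pm, judgments, tau = 1)
      acc <- jud <- NA_real_
      k_par <- 0L
      per_trial <- vapply(seq_len(n_trials), function(k)
        single_judgment_loglik(pm[[k]], judgments[[k]], 1), 0)
    } else {
      ft <- fit_tau(pm, judgments)
      tau <- ft$tau; ll <- ft$loglik
      maps <- lapply(pm, map_graph)
      acc <- accuracy_metric(maps, truths)
      jud <- judge_metric(maps, judgments)
      k_par <- 1L
      per_trial <- vapply(seq_len(n_trials), function(k)
        single_judgment_loglik(pm[[k]], judgments[[k]], tau), 0)
    }
    for (p in rownames(ll_p)) {
      ll_p[p, m] <- sum(per_trial[participants == p])
    }
    taus[m] <- tau
    rows[[m]] <- data.frame(model = m, tau = tau, loglik = ll,
                            bic = bic(ll, k_par, n_obs),
                            accuracy = acc, judge = jud,
                            stringsAsFactors = FALSE)
  }
  # ties toward simpler models: baseline, then linear, then lc/normative
  simplicity <- intersect(c("baseline",
                            grep("^(granger|lagcorr)", models, value = TRUE),
                            "lc", "normative"), models)
  nb <- best_fit_table(ll_p, tie_order = simplicity)
  tab <- do.call(rbind, rows[models])
  tab$n_best <- as.integer(nb[tab$model])
  rownames(tab) <- NULL
  list(table = tab, ll_participant = ll_p, taus = taus, posteriors = posteriors)
}
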
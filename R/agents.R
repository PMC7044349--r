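#' The packaged 23-network test battery
#'
#' A battery of 23 three-variable causal graphs spanning single causes,
#' chains, common causes, common effects, feedback loops and cycles, with 54
#' of 138 ordered-pair slots carrying a link (density 0.39), 1-4 links per
#' network and near-balanced regular/inverse signs. The battery is synthetic:
#' the individual structures were constructed to satisfy those aggregate
#' design properties, not transcribed from an experimental stimulus set (see
#' the packaged JSON's description field). The two single-cause networks are
#' also exposed as practice items via the `"practice"` attribute.
#'
#' @return Named list of 23 `causal_graph` objects, with attribute
#'   `practice` (a named list of the two single-cause graphs).
#' @examples
#' nets <- fixture_networks()
#' length(nets) # 23
#' sum(vapply(nets, function(g) sum(g != 0), 0)) # 54 links
#' @export
fixture_networks <- function() {
  path <- system.file("extdata", "test_networks_synthetic.json",
                      package = "ounet", mustWork = TRUE)
  spec <- jsonlite::read_json(path)
  vars <- unlist(spec$variables)
  nets <- lapply(spec$networks, function(nw) {
    causal_graph(vars, unlist(nw$edges))
  })
  names(nets) <- vapply(spec$networks, `[[`, "", "name")
  practice <- nets[unlist(spec$practice)]
  structure(nets, practice = practice)
}

#' Intervention-policy configuration for synthetic agents
#'
#' Describes how a simulated participant intervenes during a trial: how many
#' hold episodes, how long they last, which values they hold at, and how much
#' of an episode is spent at a constant value. Defaults emulate observed
#' human play: on average 4.94 interventions per trial, mean duration 3.46 s
#' (SD 3 s), dragging a slider from rest to an extreme (-100 or +100),
#' holding it there, and about half the time sweeping on to the opposite
#' extreme (making the intervention range bimodal around one and two full
#' half-scales); roughly 71.2% of 100 ms windows within an episode repeat the
#' previous value.
#'
#' @param interventions_mean Mean episodes per trial (shifted Poisson:
#'   `1 + Poisson(mean - 1)`). Default 4.94.
#' @param duration_mean_s,duration_sd_s Log-normal episode duration moments
#'   in seconds. Defaults 3.46 and 3.0.
#' @param hold_values Candidate hold targets (slider units). Default
#'   `c(-100, 100)`.
#' @param hold_constant_frac Fraction of within-episode ticks at an unchanged
#'   value; the remainder is spent ramping. Default 0.712.
#' @param second_sweep_prob Probability an episode continues to the opposite
#'   extreme after the first hold. Default 0.5.
#' @param one_at_a_time Forbid simultaneous interventions. Default `TRUE`.
#' @param ensure_coverage Guarantee every variable is intervened on at least
#'   once per trial. Default `TRUE`.
#' @param dt_ms Tick length in milliseconds. Default 100.
#' @return Object of class `policy_config`.
#' @export
policy_config <- function(interventions_mean = 4.94,
                          duration_mean_s = 3.46, duration_sd_s = 3.0,
                          hold_values = c(-100, 100),
                          hold_constant_frac = 0.712,
                          second_sweep_prob = 0.5,
                          one_at_a_time = TRUE,
                          ensure_coverage = TRUE,
                          dt_ms = 100) {
  stopifnot(interventions_mean >= 0, duration_mean_s > 0, duration_sd_s >= 0,
            length(hold_values) >= 1,
            hold_constant_frac >= 0, hold_constant_frac <= 1,
            second_sweep_prob >= 0, second_sweep_prob <= 1)
  structure(list(interventions_mean = interventions_mean,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s,
                 hold_values = hold_values,
                 hold_constant_frac = hold_constant_frac,
                 second_sweep_prob = second_sweep_prob,
                 one_at_a_time = one_at_a_time,
                 ensure_coverage = ensure_coverage,
                 dt_ms = dt_ms),
            class = "policy_config")
}

# values of one episode: ramp from 0 to a hold target, optionally sweep on
# to the opposite extreme; ramp ticks sized by 1 - hold_constant_frac.
episode_values <- function(len, cfg) {
  target <- sample(cfg$hold_values, 1L)
  # r ramp entries yield r - 1 changed windows, hence the + 1
  ramp_total <- max(1L, round((1 - cfg$hold_constant_frac) * (len - 1L)) + 1L)
  two_phase <- len >= 10L && runif(1) < cfg$second_sweep_prob &&
    length(cfg$hold_values) > 1L
  if (!two_phase) {
    r <- min(ramp_total, len - 1L)
    vals <- c(seq(0, target, length.out = r + 1L)[-1L], rep(target, len - r))
  } else {
    opposite <- if (-target %in% cfg$hold_values) -target
                else sample(setdiff(cfg$hold_values, target), 1L)
    len1 <- len %/% 2L
    r1 <- max(1L, min(ramp_total %/% 2L, len1 - 1L))
    r2 <- max(1L, min(ramp_total - r1, len - len1 - 1L))
    vals <- c(seq(0, target, length.out = r1 + 1L)[-1L],
              rep(target, len1 - r1),
              seq(target, opposite, length.out = r2 + 1L)[-1L],
              rep(opposite, len - len1 - r2))
  }
  vals[seq_len(len)]
}

#' Sample an intervention schedule from a policy
#'
#' Draws the number of hold episodes, their durations, their target variables
#' (covering every variable at least once when configured) and their values,
#' and packs them without overlap into the trial, with uniformly random gaps.
#' If the drawn episodes cannot fit, trailing episodes are dropped with a
#' warning.
#'
#' @param cfg A [policy_config()].
#' @param ticks Trial length T.
#' @param variables Variable names.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return An [intervention_schedule()].
#' @export
sample_schedule <- function(cfg, ticks, variables, seed = NULL) {
  n_vars <- length(variables)
  tick_per_s <- 1000 / cfg$dt_ms
  with_seed(seed, {
    n_int <- if (cfg$interventions_mean <= 1) {
      rpois(1, cfg$interventions_mean)
    } else 1L + rpois(1, cfg$interventions_mean - 1)
    if (cfg$ensure_coverage) n_int <- max(n_int, n_vars)
    if (n_int > 0L) {
      targets <- c(sample(variables, min(n_vars, n_int)),
                   if (n_int > n_vars) sample(variables, n_int - n_vars,
                                              replace = TRUE))
      targets <- sample(targets) # shuffle coverage block into the rest
      cv <- cfg$duration_sd_s / cfg$duration_mean_s
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(cfg$duration_mean_s) - sdlog^2 / 2
      dur <- pmax(5L, round(rlnorm(n_int, meanlog, sdlog) * tick_per_s))
      while (n_int > 0L && sum(dur) > 0.9 * ticks) {
        n_int <- n_int - 1L
        dur <- dur[seq_len(n_int)]
        warning("infeasible packing: dropping an episode")
      }
    }
    if (n_int == 0L) {
      intervention_schedule()
    } else {
      targets <- targets[seq_len(n_int)]
      free <- ticks - sum(dur)
      cuts <- sort(sample.int(free + 1L, n_int, replace = TRUE) - 1L)
      starts <- cuts + c(0L, cumsum(dur))[seq_len(n_int)]
      eps <- lapply(seq_len(n_int), function(k) {
        list(variable = targets[k], start = starts[k],
             end = starts[k] + dur[k],
             values = episode_values(dur[k], cfg))
      })
      intervention_schedule(eps, one_at_a_time = cfg$one_at_a_time)
    }
  })
}

#' Deterministic hold-at-extremes schedule
#'
#' A structured diagnostic policy: each variable in turn is held at the upper
#' extreme and then at the lower extreme for a fixed number of ticks, with
#' equal observation gaps in between (so relaxation after release is also
#' observed). With a seed, the variable order is shuffled; otherwise the
#' schedule is fully deterministic.
#'
#' @param ticks Trial length T.
#' @param variables Variable names.
#' @param hold_ticks Length of each hold episode. Default 30 (3 s).
#' @param extremes Hold values. Default `c(100, -100)`.
#' @param seed Optional seed shuffling the variable order.
#' @return An [intervention_schedule()].
#' @export
hold_extremes_schedule <- function(ticks, variables, hold_ticks = 30,
                                   extremes = c(100, -100), seed = NULL) {
  ord <- if (is.null(seed)) variables
         else with_seed(seed, sample(variables))
  n_ep <- length(ord) * length(extremes)
  need <- n_ep * hold_ticks
  if (need > ticks) stop_contract("holds do not fit into the trial")
  gap <- (ticks - need) %/% (n_ep + 1L)
  eps <- list()
  pos <- gap
  for (v in ord) {
    for (e in extremes) {
      eps[[length(eps) + 1L]] <-
        list(variable = v, start = pos, end = pos + hold_ticks, values = e)
      pos <- pos + hold_ticks + gap
    }
  }
  intervention_schedule(eps)
}

#' Simulate one experiment-like trial
#'
#' Samples an intervention schedule from the policy and unrolls the OU
#' network under it (strength magnitude 1 by default, matching the
#' experimental reference conditions of `omega = 0.1`, `sigma = 5`).
#'
#' @param graph True `causal_graph` of the trial.
#' @param params [ou_params()]. Default `ou_params()`.
#' @param cfg [policy_config()] used to sample the schedule; ignored when
#'   `schedule` is supplied.
#' @param ticks Trial length. Default 450.
#' @param seed Master seed for schedule and noise.
#' @param schedule Optional fixed [intervention_schedule()].
#' @param magnitude Strength magnitude. Default 1.
#' @return An `ou_trajectory` with the schedule attached as attribute
#'   `"schedule"`.
#' @export
generate_trial <- function(graph, params = ou_params(), cfg = policy_config(),
                           ticks = 450, seed = NULL, schedule = NULL,
                           magnitude = 1) {
  if (is.null(schedule)) {
    schedule <- sample_schedule(cfg, ticks, graph_variables(graph),
                                seed = derive_seed(seed, "schedule"))
  }
  traj <- simulate_ou(graph, params, schedule, ticks,
                      seed = derive_seed(seed, "noise"), magnitude = magnitude)
  attr(traj, "schedule") <- schedule
  traj
}

#' Sample a simulated participant's judgment from a model
#'
#' Draws one structure from the model's softmax choice rule: a whole graph
#' for a `graph_posterior`, or independent per-pair labels for an
#' `edge_posterior`.
#'
#' @param post A `graph_posterior` or `edge_posterior`.
#' @param tau Softmax temperature, > 0.
#' @param seed Integer seed.
#' @return A `causal_graph` holding the judged labels.
#' @export
generate_judgments <- function(post, tau, seed = NULL) {
  with_seed(seed, {
    if (inherits(post, "graph_posterior")) {
      p <- choice_distribution(post, tau)
      k <- sample.int(length(p), 1L, prob = p)
      labs <- enumerate_graph_labels(post$variables)
      causal_graph(post$variables, setNames(labs[k, ], colnames(labs)))
    } else if (inherits(post, "edge_posterior")) {
      p <- choice_distribution(post, tau)
      lab <- apply(p, 1L, function(pr) sample.int(3L, 1L, prob = pr)) - 2L
      causal_graph(attr(post, "variables"),
                   setNames(as.integer(lab), rownames(post)))
    } else stop_contract("unsupported posterior type")
  })
}

#' Configuration of a synthetic cohort
#'
#' @param n_participants Number of simulated participants.
#' @param networks List of `causal_graph`s per session (default the packaged
#'   battery); each participant sees all of them in seeded random order.
#' @param trial_ticks Ticks per trial. Default 450.
#' @param model Generating model name (`"normative"`, `"lc"`, `"baseline"`).
#' @param tau Softmax temperature of the simulated responders.
#' @param n_samples Monte-Carlo draws for the generating model's posterior.
#' @param master_seed Master seed; all per-trial seeds derive from it.
#' @param params,policy,spec Simulation parameters, intervention policy and
#'   priors.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, networks = fixture_networks(),
                          trial_ticks = 450, model = "lc", tau = 1,
                          n_samples = 1000, master_seed = 1,
                          params = ou_params(), policy = policy_config(),
                          spec = prior_spec()) {
  stopifnot(n_participants >= 1, trial_ticks >= 2,
            model %in% c("normative", "lc", "baseline"), tau > 0)
  structure(list(n_participants = n_participants, networks = networks,
                 trial_ticks = trial_ticks, model = model, tau = tau,
                 n_samples = n_samples, master_seed = master_seed,
                 params = params, policy = policy, spec = spec),
            class = "cohort_config")
}

#' Generate a synthetic behavioural cohort
#'
#' For each simulated participant: shuffle the network battery (seeded),
#' simulate each trial under the intervention policy, run the generating
#' model on the trajectory, and sample a judgment from its softmax choice
#' rule. The result is a dataset in the unit expected by [compare_models()];
#' optionally it is also written to disk as JSON-lines plus trajectory CSVs
#' via [write_dataset()].
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Optional output directory.
#' @return List of trial records (`participant`, `trial`, `network`,
#'   `graph`, `trajectory`, `judgment`), invisibly also written to `out_dir`
#'   when given.
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  records <- list()
  vars <- graph_variables(cfg$networks[[1]])
  for (p in seq_len(cfg$n_participants)) {
    ord <- with_seed(derive_seed(cfg$master_seed, "order", p),
                     sample(seq_along(cfg$networks)))
    for (k in seq_along(ord)) {
      g <- cfg$networks[[ord[k]]]
      tseed <- derive_seed(cfg$master_seed, "trial", p, k)
      traj <- generate_trial(g, cfg$params, cfg$policy, cfg$trial_ticks,
                             seed = tseed)
      post <- switch(cfg$model,
        normative = normative_posterior(traj, cfg$spec, cfg$n_samples,
                                        seed = derive_seed(tseed, "mc")),
        lc = lc_posterior(traj, cfg$spec, cfg$n_samples,
                          seed = derive_seed(tseed, "mc")),
        baseline = NULL)
      judgment <- if (is.null(post)) {
        with_seed(derive_seed(tseed, "judge"), {
          labs <- enumerate_graph_labels(vars)
          kk <- sample.int(nrow(labs), 1L)
          causal_graph(vars, setNames(labs[kk, ], colnames(labs)))
        })
      } else {
        generate_judgments(post, cfg$tau, seed = derive_seed(tseed, "judge"))
      }
      records[[length(records) + 1L]] <- list(
        participant = p, trial = k,
        network = names(cfg$networks)[ord[k]] %||% ord[k],
        graph = g, trajectory = traj, judgment = judgment)
    }
  }
  if (!is.null(out_dir)) write_dataset(records, out_dir)
  records
}
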
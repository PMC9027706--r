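#' @title Seeded trials and parameter sweeps
#' @name simulation_runner
#'
#' @description
#' Runs whole simulations: builds a network of agents with per-neighbour
#' parameter heterogeneity, executes the synchronous observe-infer-act loop,
#' and aggregates trials over condition grids. Also provides the scripted
#' single-agent scenario in which two fixed neighbours emit opposite
#' hashtags.
NULL

#' Trial configuration
#'
#' Collects every knob of one multi-agent trial. Defaults are the study
#' conditions used throughout: inverse environmental volatility fixed at
#' 9.0, hashtag reliability 0.73, per-neighbour heterogeneity variance 0.1.
#'
#' @param N Number of agents.
#' @param p Erdős–Rényi connection probability.
#' @param T_steps Number of timesteps.
#' @param gamma_mean Mean epistemic confirmation bias; each agent's
#'   per-neighbour values are normal draws around it.
#' @param omega_soc_mean Mean inverse social volatility, sampled the same
#'   way.
#' @param omega_idea Inverse environmental volatility (not sampled).
#' @param ph Hashtag reliability in (0, 1).
#' @param eta Habit learning rate.
#' @param heterogeneity_variance Variance (not SD) of the per-neighbour
#'   normal draws for `gamma` and `omega_soc`.
#' @param idea_init `"flat"` for a 0.5/0.5 initial Idea belief for every
#'   agent, or a length-2 numeric `c(lo, hi)` to draw each agent's initial
#'   Idea1 belief uniformly from that interval.
#' @param action_selection How actions are drawn from the control
#'   posteriors. `"hybrid"` (default) samples the tweet from its marginal
#'   (posting probability proportional to the Idea belief) while taking the
#'   maximum-probability attendance action (the conventional deterministic
#'   selection of discrete active-inference agents, which is what produces
#'   sustained preferential attendance); `"deterministic"` takes the argmax
#'   of both marginals; `"sample"` draws both. Bootstrap actions at t = 0
#'   are always sampled.
#' @param policy_precision Inverse temperature multiplying the negative
#'   expected free energy in the policy posterior (default 16, the
#'   conventional setting for discrete active-inference agents); the habit
#'   and tweet-link log priors are not scaled.
#' @param seed Integer seed; the whole trial is a deterministic function of
#'   the configuration including the seed.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(N = 15L, p = 0.2, T_steps = 100L,
                         gamma_mean = 3.5, omega_soc_mean = 0.6,
                         omega_idea = 9.0, ph = 0.73, eta = 0,
                         heterogeneity_variance = 0.1,
                         idea_init = "flat",
                         action_selection = c("hybrid", "deterministic",
                                              "sample"),
                         policy_precision = 16,
                         seed = 1L) {
  action_selection <- match.arg(action_selection)
  if (policy_precision < 0) .stopf("`policy_precision` must be non-negative")
  if (T_steps < 1L) .stopf("`T_steps` must be at least 1")
  if (min(gamma_mean, omega_soc_mean, omega_idea, eta) < 0)
    .stopf("parameter means must be non-negative")
  if (ph <= 0 || ph >= 1) .stopf("`ph` must lie strictly in (0, 1)")
  if (heterogeneity_variance < 0) .stopf("variance must be non-negative")
  if (is.numeric(idea_init)) {
    if (length(idea_init) != 2L || idea_init[1L] > idea_init[2L] ||
        idea_init[1L] < 0 || idea_init[2L] > 1)
      .stopf("numeric `idea_init` must be an interval c(lo, hi) within [0, 1]")
  } else if (!identical(idea_init, "flat")) {
    .stopf("`idea_init` must be \"flat\" or a numeric interval c(lo, hi)")
  }
  structure(list(N = as.integer(N), p = p, T_steps = as.integer(T_steps),
                 gamma_mean = gamma_mean, omega_soc_mean = omega_soc_mean,
                 omega_idea = omega_idea, ph = ph, eta = eta,
                 heterogeneity_variance = heterogeneity_variance,
                 idea_init = idea_init,
                 action_selection = action_selection,
                 policy_precision = policy_precision,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Sample per-neighbour parameters around a condition mean
#'
#' K independent normal draws with the given mean and variance, clipped
#' below at `floor` so precisions stay positive. With variance 0 the mean is
#' repeated.
#'
#' @param mean Condition-level mean.
#' @param variance Variance of the draws.
#' @param K Number of draws (one per neighbour).
#' @param floor Lower clip (default 0.05).
#' @return Numeric vector of length K.
#' @export
sample_agent_parameters <- function(mean, variance, K, floor = 0.05) {
  if (variance < 0) .stopf("`variance` must be non-negative")
  if (variance == 0) return(rep(mean, K))
  pmax(stats::rnorm(K, mean, sqrt(variance)), floor)
}

# categorical draw by inverse CDF; `u` in [0,1). Gives every agent its own
# pre-drawn uniforms so the trajectory is invariant to the order in which
# agents are processed within a timestep.
.sample_categorical <- function(u, p) {
  findInterval(u, cumsum(p / sum(p)), left.open = FALSE) + 1L
}

#' Build agents, initial beliefs, and bootstrap actions for a trial
#'
#' Generates the topology, samples each agent's per-neighbour `gamma` and
#' `omega_soc` vectors, sets the initial Idea belief per `idea_init`, and
#' samples the bootstrap action taken before any observation: the first
#' tweet from the initial Idea belief through the identity link, the first
#' attendance uniformly. Assumes the RNG has been seeded by the caller
#' ([run_trial()] does this).
#'
#' @param config A `trial_config`.
#' @return List with `topology`, `models` (list of `agent_model`),
#'   `beliefs` (list of `belief_state`), `actions` (list of `action_pair`),
#'   and `params` (realised per-agent parameter vectors).
#' @export
initialize_trial <- function(config) {
  topo <- generate_er_network(config$N, config$p)
  models <- vector("list", config$N)
  beliefs <- vector("list", config$N)
  actions <- vector("list", config$N)
  params <- vector("list", config$N)
  for (i in seq_len(config$N)) {
    K <- length(topo$neighbours[[i]])
    gam <- sample_agent_parameters(config$gamma_mean,
                                   config$heterogeneity_variance, K)
    oms <- sample_agent_parameters(config$omega_soc_mean,
                                   config$heterogeneity_variance, K)
    q1 <- if (is.numeric(config$idea_init))
      stats::runif(1L, config$idea_init[1L], config$idea_init[2L]) else 0.5
    u <- stats::runif(2L)
    act <- action_pair(.sample_categorical(u[1L], c(q1, 1 - q1)) - 1L,
                       .sample_categorical(u[2L], rep(1, K)) - 1L)
    models[[i]] <- assemble_agent_model(
      K, gam, oms, config$omega_idea, config$ph, config$eta,
      initial_idea_belief = q1, initial_action = act)
    beliefs[[i]] <- initial_beliefs(models[[i]])
    actions[[i]] <- act
    params[[i]] <- list(gamma = gam, omega_soc = oms)
  }
  list(topology = topo, models = models, beliefs = beliefs,
       actions = actions, params = params)
}

# Compact per-agent representation for the inner loop: transition matrices,
# attended 2x(2x2) content blocks with their column entropies, habits.
.compile_agent <- function(model, policy_precision = 16) {
  K <- model$K
  content <- vector("list", K)
  col_entropy <- vector("list", K)
  for (k in seq_len(K)) {
    cm <- matrix(model$likelihoods[[1L + k]]$table[2:3, , , k], nrow = 2L)
    content[[k]] <- cm
    col_entropy[[k]] <- apply(cm, 2L, .entropy)
  }
  list(K = K,
       B_idea = model$transitions[[1L]]$table,
       B_mb = lapply(seq_len(K), function(k) model$transitions[[1L + k]]$table),
       content = content,
       col_entropy = col_entropy,
       habit = model$habit_counts,
       eta = model$eta,
       prec = policy_precision)
}

# maps an action_selection mode to argmax flags for (tweet, attend)
.selection_flags <- function(mode) {
  switch(mode,
         hybrid = c(FALSE, TRUE),
         deterministic = c(TRUE, TRUE),
         sample = c(FALSE, FALSE),
         .stopf("unknown action_selection '%s'", mode))
}

# One agent's synchronous step. `obs_content` is 1 or 2 (Hashtag level of
# the attended neighbour), `att` the 1-based attended index. Mutates nothing;
# returns updated marginals, habits, and the chosen action. `u` holds the
# agent's two pre-drawn uniforms; `det` the argmax flags for (tweet, attend).
.step_agent <- function(ag, q_idea, q_mb, att, obs_content, u,
                        det = c(FALSE, TRUE)) {
  # empirical priors
  prior_idea <- ag$B_idea %*% q_idea
  for (k in seq_len(ag$K)) q_mb[[k]] <- ag$B_mb[[k]] %*% q_mb[[k]]
  # exact posterior over (attended meta-belief, Idea)
  M <- matrix(ag$content[[att]][obs_content, ], 2L, 2L)
  J <- (q_mb[[att]] %*% t(prior_idea)) * M
  s <- sum(J)
  q_mb[[att]] <- rowSums(J) / s
  q_idea <- colSums(J) / s
  # epistemic value of attending each neighbour at the predictive beliefs
  idea_pred <- as.vector(ag$B_idea %*% q_idea)
  gains <- numeric(ag$K)
  for (k in seq_len(ag$K)) {
    w <- as.vector(ag$B_mb[[k]] %*% q_mb[[k]]) %o% idea_pred
    po <- ag$content[[k]] %*% as.vector(w)
    gains[k] <- .entropy(po) - sum(w * ag$col_entropy[[k]])
  }
  # policy posterior: separable into control marginals because the expected
  # free energy depends only on the attendance component and the prior is a
  # product of the Idea posterior (tweet link) and the habit expectation
  tweet_marg <- .softmax(.log_floor(q_idea))
  attend_marg <- .softmax(ag$prec * gains + .log_floor(ag$habit / sum(ag$habit)))
  tweet <- if (det[1L]) which.max(tweet_marg) - 1L else
    .sample_categorical(u[1L], tweet_marg) - 1L
  attend <- if (det[2L]) which.max(attend_marg) - 1L else
    .sample_categorical(u[2L], attend_marg) - 1L
  ag$habit <- ag$habit + ag$eta * attend_marg
  list(ag = ag, q_idea = as.vector(q_idea), q_mb = q_mb,
       tweet = tweet, attend = attend, attend_marg = attend_marg)
}

#' Run one seeded multi-agent trial
#'
#' Seeds the RNG, builds the network and agents, then iterates the
#' synchronous loop for `T_steps` timesteps: observations are routed from
#' the previous timestep's action snapshot, every agent updates its beliefs
#' and samples an action, and habits are incremented. All agents read the
#' t-1 snapshot, so within-timestep processing order is immaterial.
#'
#' @param config A `trial_config`.
#' @return Object of class `opinion_trial`: matrices `beliefs` (T x N
#'   posterior probability of Idea1), `tweets`, `attends` (T x N, 0-based
#'   levels), `mb` (list of T x K matrices of meta-belief-in-Idea1 per
#'   agent), `habits` (final counts per agent), plus `topology`, `params`,
#'   and `config`.
#' @examples
#' tr <- run_trial(trial_config(N = 5, p = 0.8, T_steps = 10, seed = 42))
#' polarisation_index(final_idea_beliefs(tr))
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  st <- initialize_trial(config)
  N <- config$N
  TT <- config$T_steps
  det <- .selection_flags(config$action_selection)
  agents <- lapply(st$models, .compile_agent, config$policy_precision)
  q_idea <- lapply(st$beliefs, `[[`, "idea")
  q_mb <- lapply(st$beliefs, `[[`, "metabelief")
  tweets <- matrix(NA_integer_, TT, N)
  attends <- matrix(NA_integer_, TT, N)
  beliefs <- matrix(NA_real_, TT, N)
  mb_rec <- lapply(agents, function(a) matrix(NA_real_, TT, a$K))
  prev_tweet <- vapply(st$actions, `[[`, integer(1L), "tweet")
  prev_attend <- vapply(st$actions, `[[`, integer(1L), "attend")
  nb <- st$topology$neighbours
  for (t in seq_len(TT)) {
    u <- matrix(stats::runif(2L * N), 2L, N)
    new_tweet <- integer(N)
    new_attend <- integer(N)
    for (i in seq_len(N)) {
      att <- prev_attend[i] + 1L
      j <- nb[[i]][att]
      res <- .step_agent(agents[[i]], q_idea[[i]], q_mb[[i]], att,
                         prev_tweet[j] + 1L, u[, i], det)
      agents[[i]] <- res$ag
      q_idea[[i]] <- res$q_idea
      q_mb[[i]] <- res$q_mb
      new_tweet[i] <- res$tweet
      new_attend[i] <- res$attend
      beliefs[t, i] <- res$q_idea[1L]
      mb_rec[[i]][t, ] <- vapply(res$q_mb, `[`, numeric(1L), 1L)
    }
    tweets[t, ] <- new_tweet
    attends[t, ] <- new_attend
    prev_tweet <- new_tweet
    prev_attend <- new_attend
  }
  structure(list(config = config, topology = st$topology, params = st$params,
                 beliefs = beliefs, mb = mb_rec, tweets = tweets,
                 attends = attends,
                 habits = lapply(agents, `[[`, "habit"),
                 seed = config$seed),
            class = "opinion_trial")
}

#' Final Idea1 beliefs of a trial
#'
#' @param trial An `opinion_trial`.
#' @return Numeric vector over agents of the final-timestep posterior
#'   probability of Idea1.
#' @export
final_idea_beliefs <- function(trial) {
  trial$beliefs[nrow(trial$beliefs), ]
}

#' Scripted single-agent scenario with two opposing neighbours
#'
#' One focal agent faces two fixed information sources: neighbour 1 always
#' posts Hashtag1, neighbour 2 always Hashtag2, and the focal agent reads
#' whichever it attends to (Null on the other channel). Beliefs start flat,
#' habit learning is off, and the inverse environmental volatility is 9.0.
#' The same `gamma`/`omega_soc` value is used for both channels. This
#' isolates how confirmation bias and assumed social volatility shape belief
#' convergence and attendance patterns.
#'
#' @param gamma Epistemic confirmation bias (scalar, both neighbours).
#' @param omega_soc Inverse social volatility (scalar, both neighbours).
#' @param T_steps Number of timesteps (default 100).
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param ph Hashtag reliability (default 0.73).
#' @return An `opinion_trial` with one column per series (N = 1) and `mb`
#'   holding the focal agent's two meta-belief trajectories.
#' @export
run_single_agent_scenario <- function(gamma, omega_soc, T_steps = 100L,
                                      seed = NULL, ph = 0.73,
                                      action_selection = c("hybrid",
                                                           "deterministic",
                                                           "sample"),
                                      policy_precision = 16) {
  action_selection <- match.arg(action_selection)
  det <- .selection_flags(action_selection)
  if (!is.null(seed)) set.seed(seed)
  model <- assemble_agent_model(2L, rep(gamma, 2L), rep(omega_soc, 2L),
                                omega_idea = 9.0, ph = ph, eta = 0)
  ag <- .compile_agent(model, policy_precision)
  q_idea <- model$initial_marginals$idea
  q_mb <- model$initial_marginals$metabelief
  u0 <- stats::runif(2L)
  prev_attend <- .sample_categorical(u0[2L], c(1, 1)) - 1L
  beliefs <- numeric(T_steps)
  attends <- integer(T_steps)
  tweets <- integer(T_steps)
  mb_rec <- matrix(NA_real_, T_steps, 2L)
  for (t in seq_len(T_steps)) {
    att <- prev_attend + 1L
    res <- .step_agent(ag, q_idea, q_mb, att, obs_content = att,
                       u = stats::runif(2L), det = det)
    ag <- res$ag
    q_idea <- res$q_idea
    q_mb <- res$q_mb
    beliefs[t] <- q_idea[1L]
    mb_rec[t, ] <- vapply(q_mb, `[`, numeric(1L), 1L)
    attends[t] <- res$attend
    tweets[t] <- res$tweet
    prev_attend <- res$attend
  }
  structure(list(config = list(gamma = gamma, omega_soc = omega_soc,
                               T_steps = T_steps, ph = ph,
                               omega_idea = 9.0, eta = 0,
                               action_selection = action_selection,
                               seed = seed),
                 topology = NULL, params = NULL,
                 beliefs = matrix(beliefs, ncol = 1L),
                 mb = list(mb_rec),
                 tweets = matrix(tweets, ncol = 1L),
                 attends = matrix(attends, ncol = 1L),
                 habits = list(ag$habit), seed = seed),
            class = "opinion_trial")
}

#' Run a parameter sweep
#'
#' For every row of `grid` (a data.frame whose columns override
#' [trial_config()] arguments, e.g. `gamma_mean`, `omega_soc_mean`, `eta`,
#' `p`), runs `S` independent trials with seeds derived from `base_seed`,
#' the condition index, and the trial index, and aggregates the collective
#' outcome metrics.
#'
#' @param grid Data.frame of condition parameters (one row per condition).
#' @param S Trials per condition.
#' @param base_seed Root seed for the whole sweep.
#' @param reattendance `"mean"` (default) or `"max"` aggregation over agents
#'   within a trial; see [reattendance_rate()]. The mean variant is the
#'   sweep default because the per-trial maximum saturates at `T_steps` once
#'   any single agent locks onto one neighbour, hiding condition effects.
#' @param ... Further fixed arguments passed to [trial_config()].
#' @return A data.frame (class `sweep_result`): the condition columns plus
#'   `mean_polarisation`, `sd_polarisation`, `mean_reattendance`,
#'   `consensus_fraction`, `idea1_cluster_fraction`, `components_resolved`,
#'   `components_total`, and `S`.
#' @export
run_sweep <- function(grid, S, base_seed = 1L, reattendance = c("mean", "max"),
                      ...) {
  reattendance <- match.arg(reattendance)
  if (!is.data.frame(grid) || nrow(grid) == 0L) .stopf("`grid` must be a non-empty data.frame")
  if (S < 1L) .stopf("`S` must be at least 1")
  fixed <- list(...)
  out <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    rho <- numeric(S)
    ratt <- numeric(S)
    cons <- logical(S)
    resolved <- 0L
    idea1 <- 0L
    total_comp <- 0L
    for (s in seq_len(S)) {
      args <- c(as.list(grid[ci, , drop = FALSE]), fixed)
      args$seed <- .mix_seed(base_seed, ci, s)
      cfg <- do.call(trial_config, args)
      tr <- run_trial(cfg)
      fin <- final_idea_beliefs(tr)
      rho[s] <- polarisation_index(fin)
      ratt[s] <- reattendance_rate(tr$attends, per_trial = reattendance)
      cons[s] <- consensus_reached(fin)
      cl <- cluster_outcomes(tr$topology, fin)
      total_comp <- total_comp + length(cl$outcomes)
      resolved <- resolved + sum(cl$outcomes != "unresolved")
      idea1 <- idea1 + sum(cl$outcomes == "Idea1")
    }
    out[[ci]] <- cbind(
      grid[ci, , drop = FALSE],
      data.frame(mean_polarisation = mean(rho),
                 sd_polarisation = stats::sd(rho),
                 mean_reattendance = mean(ratt),
                 consensus_fraction = mean(cons),
                 idea1_cluster_fraction = if (resolved > 0) idea1 / resolved else NA_real_,
                 components_resolved = resolved,
                 components_total = total_comp,
                 S = S))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_result", class(res))
  res
}

#' @export
print.opinion_trial <- function(x, ...) {
  cat(sprintf("<opinion_trial> %d timesteps x %d agent(s); final Idea1 beliefs: %s\n",
              nrow(x$beliefs), ncol(x$beliefs),
              paste(signif(final_idea_beliefs(x), 3), collapse = " ")))
  invisible(x)
}

#' Plot belief trajectories of a trial
#'
#' Line per agent of the posterior probability of Idea1 over time.
#'
#' @param x An `opinion_trial`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.opinion_trial <- function(x, ...) {
  graphics::matplot(x$beliefs, type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "timestep", ylab = "Q(Idea = Idea1)", ...)
  graphics::abline(h = 0.5, col = "grey", lty = 2)
  invisible(x)
}
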
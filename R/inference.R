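#' @title Per-timestep inference, action selection, and habit learning
#'
#' @description
#' One agent's perception-action cycle: propagate yesterday's posterior
#' through the transition model (empirical prior), condition on today's
#' multi-modality observation (state estimation), score one-step policies by
#' expected free energy plus the habit/belief policy prior, sample an action
#' from the posterior control marginals, and increment the Dirichlet
#' attendance habits.
#'
#' @name agent_inference
NULL

#' Belief state over an agent's hidden-state factors
#'
#' @param idea Length-2 probability vector over (Idea1, Idea2).
#' @param metabelief List of K length-2 probability vectors, one per
#'   neighbour, each over (BelieveIdea1, BelieveIdea2).
#' @param self_tweet Length-2 probability vector over the agent's own tweet
#'   state.
#' @param who_attend Length-K probability vector over whom the agent attends.
#' @return Object of class `belief_state`.
#' @export
belief_state <- function(idea, metabelief, self_tweet, who_attend) {
  marg <- c(list(idea), metabelief, list(self_tweet, who_attend))
  for (m in marg) {
    if (any(m < -1e-12) || abs(sum(m) - 1) > 1e-10)
      .stopf("belief marginals must be non-negative and sum to 1")
  }
  structure(list(idea = idea, metabelief = metabelief,
                 self_tweet = self_tweet, who_attend = who_attend),
            class = "belief_state")
}

# belief state drawn from a model's initial (D) marginals
initial_beliefs <- function(model) {
  d <- model$initial_marginals
  belief_state(d$idea, d$metabelief, d$self_tweet, d$who_attend)
}

#' Tweet/attend action pair
#'
#' @param tweet Tweet content level: 0 (Hashtag1) or 1 (Hashtag2).
#' @param attend Attendance level: 0-based neighbour index.
#' @return Object of class `action_pair`.
#' @export
action_pair <- function(tweet, attend) {
  if (!tweet %in% c(0L, 1L)) .stopf("`tweet` must be 0 or 1")
  if (attend < 0L) .stopf("`attend` must be a non-negative neighbour index")
  structure(list(tweet = as.integer(tweet), attend = as.integer(attend)),
            class = "action_pair")
}

#' One timestep's multi-modality observation
#'
#' Exactly one neighbour-tweet entry is non-Null, and its index must equal
#' `who_attend`: an agent reads only the neighbour it attends to.
#'
#' @param self_tweet Own tweet observation, 0 or 1.
#' @param neighbour_tweets Length-K vector with levels 0 (Null), 1
#'   (Hashtag1), 2 (Hashtag2).
#' @param who_attend Attendance observation, 0-based neighbour index.
#' @return Object of class `observation_bundle`.
#' @export
observation_bundle <- function(self_tweet, neighbour_tweets, who_attend) {
  if (!self_tweet %in% c(0L, 1L)) .stopf("`self_tweet` must be 0 or 1")
  if (!all(neighbour_tweets %in% 0:2))
    .stopf("`neighbour_tweets` levels must be 0 (Null), 1, or 2")
  non_null <- which(neighbour_tweets != 0L)
  if (length(non_null) != 1L || non_null - 1L != who_attend)
    .stopf("exactly one neighbour tweet must be non-Null, at index `who_attend`")
  structure(list(self_tweet = as.integer(self_tweet),
                 neighbour_tweets = as.integer(neighbour_tweets),
                 who_attend = as.integer(who_attend)),
            class = "observation_bundle")
}

#' Empirical prior for the next timestep
#'
#' Propagates the previous posterior through the transition model, given the
#' previous action. Uncontrolled factors (Idea, meta-beliefs) are pushed
#' through their volatility-scaled transition matrices; the fully controlled
#' tweet and attendance states become one-hot at the corresponding action
#' component.
#'
#' @param previous A `belief_state` (previous timestep's posterior).
#' @param model An `agent_model`.
#' @param previous_action An `action_pair` taken at the previous timestep.
#' @return A `belief_state` holding the per-factor prior vectors.
#' @export
empirical_prior <- function(previous, model, previous_action) {
  K <- model$K
  B_idea <- model$transitions[[1L]]$table
  idea <- as.vector(B_idea %*% previous$idea)
  mb <- lapply(seq_len(K), function(k)
    as.vector(model$transitions[[1L + k]]$table %*% previous$metabelief[[k]]))
  belief_state(idea, mb,
               .one_hot(previous_action$tweet + 1L, 2L),
               .one_hot(previous_action$attend + 1L, K))
}

#' Posterior state beliefs given an observation
#'
#' Conditions the per-factor priors on one timestep's observation. In this
#' model every hidden-state factor is informed by at most one observation
#' modality (the attended neighbour-tweet channel jointly informs that
#' neighbour's meta-belief and the Idea; the identity modalities pin the
#' tweet and attendance states; Null channels carry nothing), so the exact
#' posterior is available by enumerating the small joint over each
#' informative modality's dependent factors and marginalising. That exact
#' update is the default. `method = "meanfield"` instead runs the
#' coordinate-ascent fixed-point iteration on the factorised posterior
#' (log-space messages, initialised at the prior); it converges to a product
#' approximation that is close to, but not identical with, the exact
#' marginals.
#'
#' @param prior A `belief_state` of per-factor priors (see
#'   [empirical_prior()]).
#' @param obs An `observation_bundle`.
#' @param model An `agent_model`.
#' @param tol Convergence tolerance on the largest marginal change
#'   (mean-field only).
#' @param max_iter Iteration cap (mean-field only).
#' @param method `"exact"` (default) or `"meanfield"`.
#' @return A `belief_state` of posterior marginals.
#' @export
update_state_beliefs <- function(prior, obs, model, tol = 1e-6, max_iter = 10L,
                                 method = c("exact", "meanfield")) {
  method <- match.arg(method)
  K <- model$K
  att <- obs$who_attend + 1L

  # identity modalities: posterior is the renormalised prior-times-likelihood
  st <- prior$self_tweet * .one_hot(obs$self_tweet + 1L, 2L)
  if (sum(st) <= .LOG_FLOOR)
    .stopf("self-tweet observation has zero probability under the prior")
  st <- .normalise(st)
  who <- prior$who_attend * .one_hot(att, K)
  if (sum(who) <= .LOG_FLOOR)
    .stopf("attendance observation has zero probability under the prior")
  who <- .normalise(who)

  o_att <- obs$neighbour_tweets[att]
  lik <- model$likelihoods[[1L + att]]$table  # 3 x 2 x 2 x K
  M <- lik[o_att + 1L, , , att]               # 2 (meta-belief) x 2 (Idea)

  mb <- prior$metabelief
  if (method == "exact") {
    J <- outer(prior$metabelief[[att]], prior$idea) * M
    s <- sum(J)
    if (s <= .LOG_FLOOR)
      .stopf("attended tweet observation has zero probability under the model")
    mb[[att]] <- rowSums(J) / s
    idea <- colSums(J) / s
  } else {
    q_mb <- prior$metabelief[[att]]
    q_idea <- prior$idea
    lM <- .log_floor(M)
    lp_mb <- .log_floor(prior$metabelief[[att]])
    lp_idea <- .log_floor(prior$idea)
    for (i in seq_len(max_iter)) {
      new_mb <- .softmax(lp_mb + as.vector(lM %*% q_idea))
      new_idea <- .softmax(lp_idea + as.vector(t(lM) %*% new_mb))
      delta <- max(abs(new_mb - q_mb), abs(new_idea - q_idea))
      q_mb <- new_mb
      q_idea <- new_idea
      if (delta < tol) break
    }
    mb[[att]] <- q_mb
    idea <- q_idea
  }
  # Null channels leave their meta-belief priors untouched
  belief_state(idea, mb, st, who)
}

#' Predictive beliefs under an action
#'
#' State marginals expected one step ahead, conditional on taking `action`:
#' Idea and meta-beliefs move through their transition matrices; the
#' controlled tweet and attendance states become one-hot at the action
#' components.
#'
#' @inheritParams empirical_prior
#' @param current A `belief_state` (current posterior).
#' @param action An `action_pair` under evaluation.
#' @return A `belief_state` of predictive marginals.
#' @export
predictive_beliefs <- function(current, model, action) {
  empirical_prior(current, model, action)
}

#' Expected information gain of one observation modality
#'
#' The epistemic value contributed by a modality under predictive state
#' marginals: the entropy of the predicted observation distribution minus
#' the expected ambiguity (state-conditional observation entropy), in nats.
#' Equivalently, the mutual information between the modality's observation
#' and the joint of its dependent factors.
#'
#' @param likelihood A `modality_likelihood`.
#' @param marginals List of predictive probability vectors, one per entry of
#'   `likelihood$dependent_factors`, in order.
#' @return Non-negative scalar (up to roundoff of order 1e-12).
#' @export
modality_info_gain <- function(likelihood, marginals) {
  tab <- matrix(likelihood$table, nrow = likelihood$obs_cardinality)
  joint <- Reduce(function(a, b) as.vector(outer(a, b)), marginals)
  if (length(joint) != ncol(tab))
    .stopf("marginals do not match the likelihood's dependent factors")
  po <- as.vector(tab %*% joint)
  .entropy(po) - sum(joint * apply(tab, 2L, .entropy))
}

#' Expected free energy of an action
#'
#' With a flat observation prior the utility term vanishes and the expected
#' free energy reduces to the negative summed information gain across
#' modalities, evaluated at the predictive beliefs under the action. Only
#' the attended neighbour-tweet channel can contribute: identity modalities
#' over one-hot predictive states and Null channels resolve nothing.
#'
#' @inheritParams predictive_beliefs
#' @return Scalar expected free energy (non-positive epistemic part only).
#' @export
expected_free_energy <- function(model, current, action) {
  pred <- predictive_beliefs(current, model, action)
  K <- model$K
  total <- modality_info_gain(model$likelihoods[[1L]], list(pred$self_tweet))
  for (k in seq_len(K)) {
    total <- total + modality_info_gain(
      model$likelihoods[[1L + k]],
      list(pred$metabelief[[k]], pred$idea, pred$who_attend))
  }
  total <- total + modality_info_gain(model$likelihoods[[K + 2L]],
                                      list(pred$who_attend))
  -total
}

# Fast path used by the simulation loop: information gain of attending each
# neighbour (the only non-zero term of G), computed from the 2x2 content
# block of each channel. Returns a length-K vector of gains, so that
# G(policy) = -gains[attend + 1].
.attend_info_gains <- function(model, current) {
  K <- model$K
  B_idea <- model$transitions[[1L]]$table
  idea_pred <- as.vector(B_idea %*% current$idea)
  gains <- numeric(K)
  for (k in seq_len(K)) {
    mb_pred <- as.vector(model$transitions[[1L + k]]$table %*%
                           current$metabelief[[k]])
    content <- matrix(model$likelihoods[[1L + k]]$table[2:3, , , k],
                      nrow = 2L)  # 2 obs x 4 joint (mb fastest)
    w <- as.vector(outer(mb_pred, idea_pred))
    po <- as.vector(content %*% w)
    gains[k] <- .entropy(po) - sum(w * apply(content, 2L, .entropy))
  }
  gains
}

#' Log prior over one-step policies
#'
#' Combines the two control-state priors: the tweet component follows the
#' agent's current Idea posterior through the identity tweet link (an agent
#' tweets what it believes), and the attendance component is the normalised
#' Dirichlet habit expectation `eps / sum(eps)`.
#'
#' @inheritParams predictive_beliefs
#' @return Numeric vector of log prior values aligned with `model$policies`
#'   rows.
#' @export
policy_log_prior <- function(current, model) {
  lp_tweet <- .log_floor(as.vector(model$tweet_link %*% current$idea))
  lp_att <- .log_floor(model$habit_counts / sum(model$habit_counts))
  lp_tweet[model$policies[, "tweet"] + 1L] +
    lp_att[model$policies[, "attend"] + 1L]
}

#' Policy posterior from expected free energy and prior
#'
#' `Q(policy) = softmax(-precision * G + log prior)`, with control-state
#' marginals obtained by summing policy probabilities that share a tweet or
#' attend component. The past free energy term is constant across one-step
#' future policies and is absorbed by the softmax. `precision` defaults to 1
#' (the bare posterior); the simulation runners pass the agent's policy
#' precision.
#'
#' @param efe Numeric vector of expected free energies, one per policy.
#' @param log_prior Numeric vector of log priors, same length (see
#'   [policy_log_prior()]).
#' @param model An `agent_model` supplying the policy table.
#' @param precision Non-negative inverse temperature on `-efe`.
#' @return Object of class `policy_posterior` with `policy_probs`,
#'   `tweet_marginal`, `attend_marginal`, and `efe`.
#' @export
infer_policies <- function(efe, log_prior, model, precision = 1) {
  if (length(efe) != nrow(model$policies) || length(log_prior) != length(efe))
    .stopf("`efe` and `log_prior` must have one entry per policy")
  if (!all(is.finite(efe)) || any(is.nan(log_prior)))
    .stopf("non-finite policy scores")
  if (precision < 0) .stopf("`precision` must be non-negative")
  probs <- .softmax(-precision * efe + log_prior)
  tweet_marginal <- as.vector(tapply(probs, model$policies[, "tweet"], sum))
  attend_marginal <- as.vector(tapply(probs, model$policies[, "attend"], sum))
  structure(list(policy_probs = probs,
                 tweet_marginal = tweet_marginal,
                 attend_marginal = attend_marginal,
                 efe = efe,
                 policies = model$policies),
            class = "policy_posterior")
}

#' Sample an action from the policy posterior
#'
#' Tweet and attendance actions are sampled independently from their
#' marginal control posteriors (the default). `joint = TRUE` instead samples
#' one policy from the joint posterior and takes both of its components --
#' observationally different only when the posterior carries tweet/attend
#' dependence, which the one-step separable prior here never induces.
#' Consumes the R random number stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param posterior A `policy_posterior`.
#' @param joint Sample the joint policy instead of the factorised marginals.
#' @return An `action_pair`.
#' @export
sample_action <- function(posterior, joint = FALSE) {
  if (joint) {
    i <- sample.int(length(posterior$policy_probs), 1L,
                    prob = posterior$policy_probs)
    return(action_pair(posterior$policies[i, "tweet"],
                       posterior$policies[i, "attend"]))
  }
  tweet <- sample.int(2L, 1L, prob = posterior$tweet_marginal) - 1L
  attend <- sample.int(length(posterior$attend_marginal), 1L,
                       prob = posterior$attend_marginal) - 1L
  action_pair(tweet, attend)
}

#' Dirichlet habit update
#'
#' Adds `eta` times the posterior attendance marginal to the habit
#' pseudo-counts, applied after every action: attendance choices harden into
#' a prior to repeat them.
#'
#' @param model An `agent_model`.
#' @param attend_marginal Posterior attendance marginal (length K, sums
#'   to 1).
#' @param eta Learning rate (default the model's own).
#' @return Updated habit count vector (length K).
#' @export
update_habits <- function(model, attend_marginal, eta = model$eta) {
  if (eta < 0) .stopf("`eta` must be non-negative")
  model$habit_counts + eta * attend_marginal
}
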
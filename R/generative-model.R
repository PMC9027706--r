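#' @title Agent generative models for networked opinion formation
#'
#' @description
#' Constructors for every component of a single agent's discrete POMDP
#' generative model. An agent with K neighbours carries K + 3 hidden-state
#' factors -- the binary environmental `Idea`, one binary meta-belief
#' (`MetaBelief_k`, its model of neighbour k's belief) per neighbour, its own
#' binary tweet state, and a K-level attendance state -- together with K + 2
#' observation modalities (its own tweet, one ternary Null/Hashtag1/Hashtag2
#' tweet-observation channel per neighbour, and the attendance
#' self-observation).
#'
#' Level coding convention (fixed for reproducibility of records and CSVs):
#' Idea1 = 0, Idea2 = 1; tweet contents and tweet actions Hashtag1 = 0,
#' Hashtag2 = 1; neighbour-tweet observations Null = 0, Hashtag1 = 1,
#' Hashtag2 = 2; attendance levels 0..K-1 in ascending order of neighbour
#' agent id. Internal array indices are the usual 1-based R indices.
#'
#' @name generative_model
NULL

#' Hashtag semantics matrix
#'
#' Builds the 2x2 column-stochastic mapping from a neighbour's believed Idea
#' to the hashtag they are expected to tweet: probability `ph` of tweeting
#' the hashtag matching their belief, `1 - ph` of the other. The matrix is
#' symmetric with `ph` on the diagonal.
#'
#' @param ph Hashtag reliability, strictly between 0 and 1.
#' @return Object of class `hashtag_semantics`: list with `ph` and the 2x2
#'   `matrix` (rows = tweet content Hashtag1/Hashtag2, columns = believed
#'   Idea1/Idea2).
#' @examples
#' build_hashtag_semantics(0.73)$matrix
#' @export
build_hashtag_semantics <- function(ph) {
  if (!is.numeric(ph) || length(ph) != 1L || !is.finite(ph) || ph <= 0 || ph >= 1)
    .stopf("`ph` must lie strictly in (0, 1), got %s", format(ph))
  # rows: tweet content (Hashtag1, Hashtag2); columns: believed Idea (1, 2)
  m <- matrix(c(ph, 1 - ph, 1 - ph, ph), nrow = 2L)
  structure(list(ph = ph, matrix = m), class = "hashtag_semantics")
}

.new_modality_likelihood <- function(modality_id, obs_cardinality,
                                     dependent_factors, table) {
  structure(list(modality_id = modality_id,
                 obs_cardinality = obs_cardinality,
                 dependent_factors = dependent_factors,
                 table = table),
            class = "modality_likelihood")
}

.new_factor_transition <- function(factor_id, controlled, table) {
  structure(list(factor_id = factor_id, controlled = controlled, table = table),
            class = "factor_transition")
}

#' Neighbour-tweet observation likelihood
#'
#' The likelihood for the focal agent's observation of neighbour k's tweet.
#' Dimensions: observation (Null, Hashtag1, Hashtag2) x MetaBelief_k x Idea x
#' WhoAttend. When the agent attends elsewhere (`WhoAttend != k`) the Null
#' observation is certain, so the channel carries no information. When
#' attending k, the Null row is zero and the 2x2 content block is the hashtag
#' semantics `h`, sharpened through a column softmax at precision `gamma_k`
#' on exactly those slices where the believed meta-belief matches the
#' believed Idea (`MetaBelief_k == Idea`). The unmatched slices keep `h`
#' unchanged. This asymmetric sharpening is the epistemic confirmation bias:
#' like-minded neighbours are modelled as more reliable channels.
#'
#' @param h A `hashtag_semantics` object.
#' @param gamma_k Non-negative epistemic confirmation bias precision for this
#'   neighbour.
#' @param K Focal agent's neighbour count.
#' @param k Neighbour index, 0-based (0 .. K-1).
#' @return A `modality_likelihood` with a `3 x 2 x 2 x K` table.
#' @export
build_neighbour_tweet_likelihood <- function(h, gamma_k, K, k) {
  stopifnot(inherits(h, "hashtag_semantics"))
  if (!is.numeric(gamma_k) || length(gamma_k) != 1L || gamma_k < 0 ||
      !is.finite(gamma_k))
    .stopf("`gamma_k` must be a non-negative finite scalar")
  if (K < 1L) .stopf("`K` must be at least 1")
  if (k < 0L || k >= K) .stopf("neighbour index k = %d out of range [0, %d)", k, K)
  tab <- array(0, dim = c(3L, 2L, 2L, K))
  # unattended slices: Null certain
  tab[1L, , , ] <- 1
  sharpened <- precision_scaled_columns(h$matrix, gamma_k)
  att <- k + 1L
  tab[1L, , , att] <- 0
  for (mb in 1:2) {
    for (idea in 1:2) {
      block <- if (mb == idea) sharpened else h$matrix
      tab[2:3, mb, idea, att] <- block[, mb]
    }
  }
  .new_modality_likelihood(
    modality_id = paste0("NeighbourTweet", k),
    obs_cardinality = 3L,
    dependent_factors = c(paste0("MetaBelief", k), "Idea", "WhoAttendState"),
    table = tab)
}

#' Self-tweet observation likelihood
#'
#' Identity mapping: the agent observes its own tweet content without noise.
#'
#' @return A `modality_likelihood` with a 2x2 identity table over
#'   (observation, SelfTweetState).
#' @export
build_self_tweet_likelihood <- function() {
  .new_modality_likelihood("SelfTweet", 2L, "SelfTweetState", diag(2))
}

#' Attendance observation likelihood
#'
#' Identity mapping: the agent observes unambiguously whom it is attending.
#'
#' @param K Neighbour count (>= 1).
#' @return A `modality_likelihood` with a KxK identity table over
#'   (observation, WhoAttendState).
#' @export
build_attend_likelihood <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1)
    .stopf("`K` must be at least 1")
  .new_modality_likelihood("WhoAttend", as.integer(K), "WhoAttendState",
                           diag(as.integer(K)))
}

#' Idea transition model
#'
#' Uncontrolled dynamics of the environmental Idea state: the 2x2 identity
#' softmax-scaled at precision `omega_idea` (inverse environmental
#' volatility). Higher precision means the agent believes the true Idea
#' persists; at precision 0 it expects the Idea to be resampled uniformly
#' every step.
#'
#' @param omega_idea Non-negative precision.
#' @return A `factor_transition` (uncontrolled, 2x2, column-stochastic).
#' @export
build_idea_transition <- function(omega_idea) {
  if (!is.numeric(omega_idea) || length(omega_idea) != 1L || omega_idea < 0 ||
      !is.finite(omega_idea))
    .stopf("`omega_idea` must be a non-negative finite scalar")
  .new_factor_transition("Idea", FALSE,
                         precision_scaled_columns(diag(2), omega_idea))
}

#' Meta-belief transition model
#'
#' Uncontrolled dynamics of one neighbour's believed opinion: the 2x2
#' identity softmax-scaled at precision `omega_soc_k` (inverse social
#' volatility). Low precision means the neighbour's opinion is believed to
#' drift quickly, so uncertainty about it accumulates while unattended --
#' the source of the re-attendance incentive.
#'
#' @param omega_soc_k Non-negative precision.
#' @return A `factor_transition` (uncontrolled, 2x2, column-stochastic).
#' @export
build_metabelief_transition <- function(omega_soc_k) {
  if (!is.numeric(omega_soc_k) || length(omega_soc_k) != 1L || omega_soc_k < 0 ||
      !is.finite(omega_soc_k))
    .stopf("`omega_soc_k` must be a non-negative finite scalar")
  .new_factor_transition("MetaBelief", FALSE,
                         precision_scaled_columns(diag(2), omega_soc_k))
}

#' Deterministic controlled transition
#'
#' Transition for a fully controllable factor (own tweet state, attendance
#' state): the next state equals the chosen control level regardless of the
#' previous state, `table[s', s, u] = 1` iff `s' = u`.
#'
#' @param cardinality Number of levels (>= 1).
#' @return A `factor_transition` with a `cardinality^3` array.
#' @export
build_controlled_transition <- function(cardinality) {
  if (!is.numeric(cardinality) || length(cardinality) != 1L || cardinality < 1)
    .stopf("`cardinality` must be at least 1")
  n <- as.integer(cardinality)
  tab <- array(0, dim = c(n, n, n))
  for (u in seq_len(n)) tab[u, , u] <- 1
  .new_factor_transition("controlled", TRUE, tab)
}

#' Assemble a full agent generative model
#'
#' Bundles the per-modality likelihoods, per-factor transitions, initial
#' state marginals, identity tweet link, Dirichlet attendance habit counts,
#' and the one-step policy set (all `2K` tweet/attend pairs) for an agent
#' with `K` neighbours.
#'
#' @param K Neighbour count (>= 1).
#' @param gamma Length-K vector of epistemic confirmation bias precisions,
#'   one per neighbour channel.
#' @param omega_soc Length-K vector of inverse social volatilities, one per
#'   neighbour.
#' @param omega_idea Inverse environmental volatility (scalar).
#' @param ph Hashtag reliability in (0, 1).
#' @param eta Habit learning rate (>= 0).
#' @param initial_idea_belief Probability assigned to Idea1 in the initial
#'   Idea marginal (default 0.5, a flat prior).
#' @param initial_habit_counts Positive length-K Dirichlet pseudo-counts
#'   (default all ones: an unbiased attendance prior).
#' @param initial_action Optional `action_pair` fixing the initial
#'   SelfTweetState and WhoAttendState marginals to one-hot vectors; when
#'   `NULL` both are left flat.
#' @return Object of class `agent_model`.
#' @examples
#' m <- assemble_agent_model(K = 3, gamma = c(3, 6, 9),
#'                           omega_soc = rep(0.6, 3), omega_idea = 9,
#'                           ph = 0.73, eta = 0.5)
#' length(m$likelihoods)  # 5: self tweet, 3 neighbour channels, attendance
#' nrow(m$policies)       # 6 = 2K one-step policies
#' @export
assemble_agent_model <- function(K, gamma, omega_soc, omega_idea, ph, eta,
                                 initial_idea_belief = 0.5,
                                 initial_habit_counts = rep(1, K),
                                 initial_action = NULL) {
  K <- as.integer(K)
  if (K < 1L) .stopf("`K` must be at least 1")
  if (length(gamma) != K || length(omega_soc) != K)
    .stopf("`gamma` and `omega_soc` must both have length K = %d", K)
  if (length(initial_habit_counts) != K || any(initial_habit_counts <= 0))
    .stopf("`initial_habit_counts` must be %d strictly positive values", K)
  if (!is.numeric(eta) || eta < 0) .stopf("`eta` must be non-negative")
  if (initial_idea_belief < 0 || initial_idea_belief > 1)
    .stopf("`initial_idea_belief` must lie in [0, 1]")

  h <- build_hashtag_semantics(ph)
  likelihoods <- c(
    list(build_self_tweet_likelihood()),
    lapply(seq_len(K) - 1L, function(k)
      build_neighbour_tweet_likelihood(h, gamma[k + 1L], K, k)),
    list(build_attend_likelihood(K)))
  transitions <- c(
    list(build_idea_transition(omega_idea)),
    lapply(omega_soc, build_metabelief_transition),
    list(build_controlled_transition(2L), build_controlled_transition(K)))

  init_tweet <- rep(0.5, 2)
  init_who <- rep(1 / K, K)
  if (!is.null(initial_action)) {
    init_tweet <- .one_hot(initial_action$tweet + 1L, 2L)
    init_who <- .one_hot(initial_action$attend + 1L, K)
  }
  initial_marginals <- list(
    idea = c(initial_idea_belief, 1 - initial_idea_belief),
    metabelief = replicate(K, c(0.5, 0.5), simplify = FALSE),
    self_tweet = init_tweet,
    who_attend = init_who)

  policies <- as.matrix(expand.grid(tweet = 0:1, attend = 0:(K - 1L)))

  structure(list(K = K,
                 gamma = as.numeric(gamma),
                 omega_soc = as.numeric(omega_soc),
                 omega_idea = omega_idea,
                 ph = ph,
                 eta = eta,
                 likelihoods = likelihoods,
                 transitions = transitions,
                 initial_marginals = initial_marginals,
                 tweet_link = diag(2),
                 habit_counts = as.numeric(initial_habit_counts),
                 policies = policies),
            class = "agent_model")
}

#' @export
print.agent_model <- function(x, ...) {
  cat(sprintf(
    "<agent_model> K = %d neighbours | gamma = %s | omega_soc = %s | omega_idea = %g | ph = %g | eta = %g\n",
    x$K, paste(signif(x$gamma, 3), collapse = ", "),
    paste(signif(x$omega_soc, 3), collapse = ", "),
    x$omega_idea, x$ph, x$eta))
  invisible(x)
}
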
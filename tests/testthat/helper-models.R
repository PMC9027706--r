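# Shared fixture builders. Everything is generated in code; no stored data.

# small two-neighbour agent with distinct per-neighbour biases
make_k2_model <- function(gamma = c(3, 9), omega_soc = c(0.6, 0.6),
                          omega_idea = 9, ph = 0.73, eta = 0.5) {
  assemble_agent_model(2L, gamma, omega_soc, omega_idea, ph, eta)
}

# brute-force posterior over (meta-belief, Idea) by enumerating the 4-state
# joint for the attended channel, written independently of the package's
# update path (direct products of scalar probabilities)
enumerate_joint_posterior <- function(prior_mb, prior_idea, ph, gamma_k, obs) {
  sharp <- function(col) exp(gamma_k * col) / sum(exp(gamma_k * col))
  h <- matrix(c(ph, 1 - ph, 1 - ph, ph), 2)
  post <- matrix(0, 2, 2)
  for (mb in 1:2) {
    for (idea in 1:2) {
      col <- if (mb == idea) sharp(h[, mb]) else h[, mb]
      post[mb, idea] <- prior_mb[mb] * prior_idea[idea] * col[obs]
    }
  }
  post / sum(post)
}

# random probability vectors / one-hots for property loops
rdirichlet <- function(n) {
  x <- rexp(n)
  x / sum(x)
}
rdirichlet2 <- function() rdirichlet(2L)
.one_hot_vec <- function(i, n) as.numeric(seq_len(n) == i)

# three-agent line graph 1 - 2 - 3
line3_topology <- function() {
  opinionet:::topology_from_edges(3L, rbind(c(1L, 2L), c(2L, 3L)))
}

# mutual information of an (obs x state) channel against a state prior,
# via the KL decomposition sum_o q(o) KL[q(s|o) || q(s)]
mi_kl_form <- function(channel, state_prior) {
  joint <- sweep(channel, 2L, state_prior, "*")
  po <- rowSums(joint)
  total <- 0
  for (o in seq_along(po)) {
    if (po[o] == 0) next
    cond <- joint[o, ] / po[o]
    nz <- cond > 0
    total <- total + po[o] * sum(cond[nz] * log(cond[nz] / state_prior[nz]))
  }
  total
}
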
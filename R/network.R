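#' @title Communication topology and observation routing
#' @name social_environment
#'
#' @description
#' The social environment couples the agents: an undirected Erdős–Rényi
#' graph fixes who can read whom, and each timestep every agent's
#' observation bundle is assembled from the previous timestep's actions --
#' its own tweet, its own attendance choice, and the tweet of the one
#' neighbour it attended (Null for all others).
NULL

#' Generate an Erdős–Rényi communication network
#'
#' Each unordered agent pair is connected independently with probability
#' `p`. Because an isolated agent has no observation channels or policies,
#' graphs containing an isolated node are rejected and regenerated, up to
#' `max_retries` attempts. Neighbour lists are sorted by ascending agent id,
#' which fixes the neighbour indexing used by per-neighbour parameters,
#' habits, and records. Agent ids are 1..N inside R; exported edge lists use
#' 0-based ids.
#'
#' @param N Number of agents (>= 2).
#' @param p Connection probability in (0, 1].
#' @param max_retries Regeneration attempts before giving up.
#' @return Object of class `network_topology`: list with `N`, `edges` (2
#'   column matrix of 1-based ids, source < target), and `neighbours` (list
#'   of sorted 1-based neighbour ids per agent).
#' @examples
#' set.seed(1)
#' topo <- generate_er_network(10, 0.4)
#' lengths(topo$neighbours)  # every agent has degree >= 1
#' @export
generate_er_network <- function(N, p, max_retries = 100L) {
  if (!is.numeric(N) || N < 2) .stopf("`N` must be at least 2")
  if (!is.numeric(p) || p <= 0 || p > 1)
    .stopf("`p` must lie in (0, 1]; isolated agents are not modelled")
  N <- as.integer(N)
  for (attempt in seq_len(max_retries)) {
    g <- igraph::sample_gnp(N, p, directed = FALSE)
    if (min(igraph::degree(g)) >= 1L) {
      edges <- igraph::as_edgelist(g, names = FALSE)
      edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                     pmax(edges[, 1L], edges[, 2L]))
      storage.mode(edges) <- "integer"
      colnames(edges) <- c("source", "target")
      edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
      nb <- lapply(seq_len(N), function(i)
        sort(as.integer(igraph::neighbors(g, i))))
      return(structure(list(N = N, edges = edges, neighbours = nb),
                       class = "network_topology"))
    }
  }
  .stopf("could not generate an isolation-free graph in %d attempts (N = %d, p = %g)",
         max_retries, N, p)
}

# topology from a raw edge list (used by the CSV reader and tests)
topology_from_edges <- function(N, edges) {
  N <- as.integer(N)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  storage.mode(edges) <- "integer"
  if (any(edges[, 1L] == edges[, 2L])) .stopf("self-loops are not allowed")
  if (any(edges < 1L) || any(edges > N)) .stopf("edge ids out of range 1..%d", N)
  edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  colnames(edges) <- c("source", "target")
  nb <- lapply(seq_len(N), function(i)
    sort(unique(c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L]))))
  if (any(lengths(nb) == 0L)) .stopf("every agent must have degree >= 1")
  structure(list(N = N, edges = edges, neighbours = nb),
            class = "network_topology")
}

#' Route previous actions into per-agent observation bundles
#'
#' A pure function of the topology and the previous timestep's action list:
#' agent i observes its own previous tweet, its own previous attendance
#' choice, and -- on exactly the channel it attended -- the previous tweet
#' of that neighbour, recoded from tweet level (0/1) to observation level
#' (1/2, with 0 reserved for Null). All other neighbour channels read Null.
#'
#' @param topology A `network_topology`.
#' @param actions List of N `action_pair`s, where `attend` is each agent's
#'   0-based neighbour index.
#' @return List of N `observation_bundle`s.
#' @export
route_observations <- function(topology, actions) {
  if (length(actions) != topology$N)
    .stopf("need one action per agent")
  lapply(seq_len(topology$N), function(i) {
    nb <- topology$neighbours[[i]]
    K <- length(nb)
    a <- actions[[i]]
    if (a$attend < 0L || a$attend >= K)
      .stopf("agent %d attend index %d out of range for degree %d",
             i, a$attend, K)
    j <- nb[a$attend + 1L]
    nt <- integer(K)
    nt[a$attend + 1L] <- actions[[j]]$tweet + 1L
    observation_bundle(a$tweet, nt, a$attend)
  })
}

#' Write / read a topology as an edge-list CSV
#'
#' Two-column CSV with header `source,target` and 0-based agent ids.
#'
#' @param topology A `network_topology`.
#' @param path File path.
#' @export
write_topology_csv <- function(topology, path) {
  df <- data.frame(source = topology$edges[, 1L] - 1L,
                   target = topology$edges[, 2L] - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology_csv
#' @param N Number of agents (ids in the file must fall in 0..N-1).
#' @export
read_topology_csv <- function(path, N) {
  df <- utils::read.csv(path)
  if (!all(c("source", "target") %in% names(df)))
    .stopf("edge-list CSV needs `source` and `target` columns")
  topology_from_edges(N, cbind(df$source + 1L, df$target + 1L))
}
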
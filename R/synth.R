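# Seeded synthetic-network generators. These provide every input needed to
# exercise the backbone models: a fixed multi-scale weighted toy network, a
# block-structured bipartite network, a stochastic block model, and a
# preferential-attachment network. All are pure functions of their
# parameters and seed.

#' Multi-scale weighted toy network
#'
#' A fixed 10-node weighted network with two clusters bridged by a strong
#' edge: a low-weight cluster (nodes 1-5, spoke weights 10, within-cluster
#' weights 1 around hub node 1) and a high-weight cluster (nodes 6-10,
#' spoke weights 100, within-cluster weights 10 around hub node 6), joined
#' by an edge of weight 75 between the two hubs. Its edge weights are
#' long-tailed and multi-scale, which makes it a sharp test case: a global
#' mean threshold keeps only the heavy cluster, while the disparity filter
#' recovers the full two-hub star structure.
#'
#' @return A 10x10 symmetric adjacency matrix with node labels "1".."10",
#'   21 undirected edges, and zero diagonal.
#' @examples
#' toy_weighted()["1", "6"]
#' @export
toy_weighted <- function() {
  m <- matrix(c(
    0, 10, 10, 10, 10, 75, 0, 0, 0, 0,
    10, 0, 1, 1, 1, 0, 0, 0, 0, 0,
    10, 1, 0, 1, 1, 0, 0, 0, 0, 0,
    10, 1, 1, 0, 1, 0, 0, 0, 0, 0,
    10, 1, 1, 1, 0, 0, 0, 0, 0, 0,
    75, 0, 0, 0, 0, 0, 100, 100, 100, 100,
    0, 0, 0, 0, 0, 100, 0, 10, 10, 10,
    0, 0, 0, 0, 0, 100, 10, 0, 10, 10,
    0, 0, 0, 0, 0, 100, 10, 10, 0, 10,
    0, 0, 0, 0, 0, 100, 10, 10, 10, 0
  ), nrow = 10)
  dimnames(m) <- list(as.character(1:10), as.character(1:10))
  m
}

#' Block-structured random bipartite network
#'
#' Agents and artifacts are split into matched groups; each agent-artifact
#' cell is an independent Bernoulli draw with probability `p_in` when the
#' two belong to the same group and `p_out` otherwise. With the defaults
#' (3 groups of 10 agents and 25 artifacts, 80% within / 20% between) the
#' projection is dense and hides the group structure, which bipartite null
#' models recover.
#'
#' @param groups Number of groups.
#' @param agents_per,artifacts_per Agents and artifacts per group.
#' @param p_in,p_out Within- and between-group edge probabilities.
#' @param seed Optional integer seed.
#' @return A binary incidence matrix (labels `a1..`, `f1..`) with a
#'   `groups` attribute holding the agent group assignment.
#' @examples
#' B <- bipartite_blocks(seed = 1)
#' dim(B)
#' @export
bipartite_blocks <- function(groups = 3, agents_per = 10, artifacts_per = 25,
                             p_in = 0.8, p_out = 0.2, seed = NULL) {
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1)) {
    abort("`p_in` and `p_out` must be probabilities.")
  }
  if (any(c(groups, agents_per, artifacts_per) < 1)) {
    abort("group counts and sizes must be at least 1.")
  }
  ga <- rep(seq_len(groups), each = agents_per)
  gf <- rep(seq_len(groups), each = artifacts_per)
  pmat <- ifelse(outer(ga, gf, "=="), p_in, p_out)
  B <- with_seed_if(seed, matrix(rbinom(length(pmat), 1, pmat), nrow(pmat)))
  storage.mode(B) <- "double"
  dimnames(B) <- list(paste0("a", seq_along(ga)), paste0("f", seq_along(gf)))
  attr(B, "groups") <- ga
  B
}

#' Stochastic block model network
#'
#' An unweighted, undirected network with planted communities: within-block
#' edges appear with probability `p_in`, between-block edges with `p_out`.
#' Delegates to igraph's SBM sampler.
#'
#' @param n Number of nodes (must equal `sum(block_sizes)`).
#' @param block_sizes Integer vector of block sizes.
#' @param p_in,p_out Within- and between-block edge probabilities.
#' @param seed Optional integer seed.
#' @return A binary symmetric adjacency matrix with a `blocks` attribute.
#' @export
sbm_graph <- function(n = 60, block_sizes = c(20, 20, 20),
                      p_in = 0.75, p_out = 0.25, seed = NULL) {
  if (sum(block_sizes) != n) abort("`block_sizes` must sum to `n`.")
  k <- length(block_sizes)
  pref <- matrix(p_out, k, k)
  diag(pref) <- p_in
  g <- with_seed_if(seed, igraph::sample_sbm(n, pref.matrix = pref,
                                             block.sizes = block_sizes))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(A) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  storage.mode(A) <- "double"
  attr(A, "blocks") <- rep(seq_len(k), block_sizes)
  A
}

#' Preferential-attachment network
#'
#' An unweighted, undirected scale-free network grown by preferential
#' attachment (each new node attaches `m` edges to existing nodes with
#' probability proportional to degree), via igraph's sampler. Multi-edges
#' are collapsed, so the edge count lies between
#' \eqn{nm - m(m+1)/2} and \eqn{nm}.
#'
#' @param n Number of nodes.
#' @param m Edges attached by each new node.
#' @param seed Optional integer seed.
#' @return A binary symmetric adjacency matrix.
#' @export
pa_graph <- function(n = 60, m = 3, seed = NULL) {
  g <- with_seed_if(seed, igraph::sample_pa(n, m = m, directed = FALSE))
  g <- igraph::simplify(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(A) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  storage.mode(A) <- "double"
  A
}
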
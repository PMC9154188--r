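# Null models for weighted bipartite projections. Each model compares the
# observed co-occurrence count P_ij of an agent pair to its distribution
# under a null that constrains the bipartite margins in some way, and
# returns upper/lower-tail p-values for every dyad (zero-weight dyads
# included, so that signed extraction can flag significantly weak pairs).

bipartite_desc <- function(B) {
  sprintf("the weighted projection of an unweighted bipartite network containing %d agents and %d artifacts",
          nrow(B), ncol(B))
}

bipartite_result <- function(B, model, params, tail_fun) {
  P <- project(B)
  et <- edge_table(P, keep_zero = TRUE)
  idx_from <- match(et$from, rownames(B))
  idx_to <- match(et$to, rownames(B))
  tails <- purrr::map2(idx_from, idx_to, function(i, j) tail_fun(i, j, P[i, j]))
  et$p_upper <- purrr::map_dbl(tails, "p_upper")
  et$p_lower <- purrr::map_dbl(tails, "p_lower")
  new_backbone_result(
    et,
    nodes = rownames(B),
    model = model,
    params = c(params, list(n_agents = nrow(B), n_artifacts = ncol(B))),
    orig = P,
    tested = "all",
    network_desc = bipartite_desc(B)
  )
}

finish_bipartite <- function(res, alpha, signed, mtc, narrative) {
  if (is.null(alpha)) return(res)
  bb <- extract_backbone(res, alpha = alpha, signed = signed, mtc = mtc)
  if (narrative) cat(narrative_text(bb))
  bb
}

#' Stochastic degree sequence model (SDSM) backbone
#'
#' Null model for a bipartite projection in which random incidence matrices
#' match the observed agent and artifact degrees *on average*. The cell
#' probabilities Q come from the maximum-entropy bipartite configuration
#' model ([bicm_fit()]); under the null, the co-occurrence count of agents
#' i and j is Poisson-binomial with per-artifact probabilities
#' \eqn{Q_{ik} Q_{jk}}, and tail probabilities are computed exactly
#' ([poisson_binomial_tail()]). The model is fully deterministic.
#'
#' @param B Binary incidence matrix (agents x artifacts), or coercible.
#' @param alpha Significance level, or `NULL` to return the p-value object.
#' @param signed Logical; two-tailed signed extraction.
#' @param mtc Multiple-test correction, see [adjust_pvalues()].
#' @param narrative Logical; print manuscript-ready text.
#' @param tol,max_iter Passed to [bicm_fit()].
#' @return A [`backbone`][tidy.backbone], or a `backbone_result` when
#'   `alpha = NULL`.
#' @examples
#' B <- bipartite_blocks(groups = 2, agents_per = 5, artifacts_per = 8, seed = 1)
#' sdsm(B, alpha = 0.1)
#' @export
sdsm <- function(B, alpha = 0.05, signed = FALSE, mtc = "none",
                 narrative = FALSE, tol = 1e-8, max_iter = 10000) {
  B <- as_incidence(B)
  Q <- bicm_fit(B, tol = tol, max_iter = max_iter)
  res <- bipartite_result(
    B, "sdsm", list(estimator = "bicm"),
    function(i, j, w) poisson_binomial_tail(Q[i, ] * Q[j, ], w)
  )
  finish_bipartite(res, alpha, signed, mtc, narrative)
}

#' Fixed row sums (hypergeometric) backbone model
#'
#' Null model that fixes the agent degrees exactly and lets each agent pick
#' its artifacts uniformly at random: the co-occurrence of agents i and j
#' with degrees \eqn{d_i, d_j} among c artifacts is hypergeometric
#' (population c, successes \eqn{d_i}, draws \eqn{d_j}).
#'
#' @inheritParams sdsm
#' @return A [`backbone`][tidy.backbone], or a `backbone_result` when
#'   `alpha = NULL`.
#' @export
fixedrow <- function(B, alpha = 0.05, signed = FALSE, mtc = "none",
                     narrative = FALSE) {
  B <- as_incidence(B)
  d <- rowSums(B)
  nc <- ncol(B)
  res <- bipartite_result(
    B, "fixedrow", list(),
    function(i, j, w) list(
      p_upper = phyper(w - 1, d[i], nc - d[i], d[j], lower.tail = FALSE),
      p_lower = phyper(w, d[i], nc - d[i], d[j])
    )
  )
  finish_bipartite(res, alpha, signed, mtc, narrative)
}

#' Fixed column sums backbone model
#'
#' Null model that fixes the artifact degrees exactly and assigns agents to
#' artifacts uniformly: artifact k with degree \eqn{f_k} among r agents
#' contains a given pair with probability
#' \eqn{\pi_k = (f_k/r)\,((f_k - 1)/(r - 1))}, and the pair's co-occurrence
#' count is Poisson-binomial over artifacts.
#'
#' @inheritParams sdsm
#' @return A [`backbone`][tidy.backbone], or a `backbone_result` when
#'   `alpha = NULL`.
#' @export
fixedcol <- function(B, alpha = 0.05, signed = FALSE, mtc = "none",
                     narrative = FALSE) {
  B <- as_incidence(B)
  r <- nrow(B)
  if (r < 2) abort("fixedcol requires at least two agents.")
  f <- colSums(B)
  pi_k <- (f / r) * pmax(f - 1, 0) / (r - 1)
  res <- bipartite_result(
    B, "fixedcol", list(),
    function(i, j, w) poisson_binomial_tail(pi_k, w)
  )
  finish_bipartite(res, alpha, signed, mtc, narrative)
}

#' Fixed fill backbone model
#'
#' Null model that fixes only the total number of 1s in the incidence
#' matrix: with fill rate \eqn{q = \sum B / (rc)}, each artifact contains a
#' given pair independently with probability \eqn{q^2}, so the
#' co-occurrence count is Binomial(c, q^2).
#'
#' @inheritParams sdsm
#' @return A [`backbone`][tidy.backbone], or a `backbone_result` when
#'   `alpha = NULL`.
#' @export
fixedfill <- function(B, alpha = 0.05, signed = FALSE, mtc = "none",
                      narrative = FALSE) {
  B <- as_incidence(B)
  q <- sum(B) / length(B)
  nc <- ncol(B)
  res <- bipartite_result(
    B, "fixedfill", list(fill = q),
    function(i, j, w) list(
      p_upper = pbinom(w - 1, nc, q^2, lower.tail = FALSE),
      p_lower = pbinom(w, nc, q^2)
    )
  )
  finish_bipartite(res, alpha, signed, mtc, narrative)
}

# One curveball trade on a list of per-agent artifact sets: pick two agents,
# pool the artifacts not shared between them, and re-deal the pool at random
# while keeping each agent's degree. Row and column sums are invariant.
curveball_trade <- function(rows) {
  pick <- sample.int(length(rows), 2)
  a <- rows[[pick[1]]]
  b <- rows[[pick[2]]]
  shared <- intersect(a, b)
  only_a <- setdiff(a, shared)
  only_b <- setdiff(b, shared)
  if (length(only_a) && length(only_b)) {
    pool <- sample(c(only_a, only_b))
    rows[[pick[1]]] <- c(shared, pool[seq_along(only_a)])
    rows[[pick[2]]] <- c(shared, pool[-seq_along(only_a)])
  }
  rows
}

rows_to_matrix <- function(rows, template) {
  M <- matrix(0, nrow(template), ncol(template), dimnames = dimnames(template))
  for (i in seq_along(rows)) M[i, rows[[i]]] <- 1
  M
}

#' Sample from the fixed degree sequence null by curveball trades
#'
#' Runs `steps` curveball trades from `B` and returns the resulting binary
#' matrix. Every trade swaps non-shared artifacts between two randomly
#' chosen agents, so the row and column sums of `B` are preserved exactly;
#' a sufficiently long trade sequence samples (asymptotically uniformly)
#' from the set of all binary matrices with those margins.
#'
#' @param B Binary incidence matrix, or coercible.
#' @param steps Number of trades (at least 1).
#' @param seed Optional integer seed; given a seed the output is
#'   deterministic and the caller's RNG state is untouched.
#' @return A binary matrix with the margins of `B`.
#' @examples
#' B <- bipartite_blocks(groups = 2, agents_per = 4, artifacts_per = 6, seed = 1)
#' Bs <- curveball_sample(B, steps = 100, seed = 42)
#' all(rowSums(Bs) == rowSums(B))
#' @export
curveball_sample <- function(B, steps = 5 * nrow(B), seed = NULL) {
  B <- as_incidence(B)
  if (length(steps) != 1 || !is.finite(steps) || steps < 1) {
    abort("`steps` must be a positive integer.")
  }
  rows <- apply(B, 1, function(x) which(x == 1), simplify = FALSE)
  rows <- with_seed_if(seed, {
    for (t in seq_len(steps)) rows <- curveball_trade(rows)
    rows
  })
  rows_to_matrix(rows, B)
}

#' Fixed degree sequence model (FDSM) backbone
#'
#' Null model that fixes both agent and artifact degrees exactly. The null
#' distribution of each pair's co-occurrence count has no closed form, so
#' p-values are estimated by Monte Carlo: a sequential curveball chain
#' ([curveball_sample()]) yields margin-preserving random incidence
#' matrices, each separated by `5 * nrow(B)` trades from the previous state.
#' Empirical p-values use the add-one estimator
#' \deqn{\hat p_{upper} = (1 + \#\{W^* \ge P_{ij}\}) / (trials + 1),}
#' which is never exactly zero and therefore safe to feed into
#' multiple-test corrections.
#'
#' When `trials` is `NULL` the number of trials is chosen automatically as
#' the smallest n for which the half-width of the 95% binomial confidence
#' interval of a p-value near `alpha` is at most `alpha/10`.
#'
#' @inheritParams sdsm
#' @param trials Number of Monte-Carlo samples, or `NULL` for the automatic
#'   rule (which then requires a non-`NULL` `alpha`).
#' @param seed Optional integer seed for the sampling chain.
#' @return A [`backbone`][tidy.backbone], or a `backbone_result` when
#'   `alpha = NULL`.
#' @export
fdsm <- function(B, alpha = 0.05, trials = NULL, seed = NULL,
                 signed = FALSE, mtc = "none", narrative = FALSE) {
  B <- as_incidence(B)
  if (is.null(trials)) {
    if (is.null(alpha)) {
      abort("automatic trial selection needs `alpha`; give `trials` explicitly when alpha = NULL.")
    }
    trials <- fdsm_auto_trials(alpha)
  }
  if (length(trials) != 1 || !is.finite(trials) || trials < 1) {
    abort("`trials` must be a positive integer.")
  }
  trials <- as.integer(trials)
  P <- project(B)
  r <- nrow(B)
  upper_idx <- upper.tri(P)
  obs <- P[upper_idx]
  ge <- le <- numeric(length(obs))
  step_block <- 5L * r
  rows <- apply(B, 1, function(x) which(x == 1), simplify = FALSE)
  rows <- with_seed_if(seed, {
    for (t in seq_len(trials)) {
      for (s in seq_len(step_block)) rows <- curveball_trade(rows)
      Bs <- rows_to_matrix(rows, B)
      Ps <- tcrossprod(Bs)
      wstar <- Ps[upper_idx]
      ge <- ge + (wstar >= obs)
      le <- le + (wstar <= obs)
    }
    rows
  })
  p_up <- (1 + ge) / (trials + 1)
  p_lo <- (1 + le) / (trials + 1)
  Pu <- Pl <- P
  Pu[upper_idx] <- p_up
  Pl[upper_idx] <- p_lo
  res <- bipartite_result(
    B, "fdsm", list(trials = trials, seed = seed),
    function(i, j, w) {
      a <- min(i, j); b <- max(i, j)
      list(p_upper = Pu[a, b], p_lower = Pl[a, b])
    }
  )
  finish_bipartite(res, alpha, signed, mtc, narrative)
}

# Smallest n with 1.96 * sqrt(alpha (1 - alpha) / n) <= alpha / 10.
fdsm_auto_trials <- function(alpha) {
  ceiling(qnorm(0.975)^2 * alpha * (1 - alpha) / (alpha / 10)^2)
}
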
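weighted_desc <- function(A) {
  sprintf("a weighted and undirected unipartite network containing %d nodes",
          nrow(A))
}

#' Global threshold backbone of a weighted network
#'
#' The simplest structural backbone model: an edge is retained when its
#' weight strictly exceeds a global threshold. The threshold may be a number
#' or a function of the full adjacency matrix (e.g. `mean`, `median`, or a
#' quantile); note that a function is evaluated over *all* cells of the
#' matrix, zeros and diagonal included, so `mean` is the mean over n^2 cells,
#' not over the edges. Global thresholds are known to behave poorly on
#' long-tailed or multi-scale weight distributions, for which the
#' [disparity()] filter is preferable.
#'
#' An optional `lower` threshold yields a signed backbone in which existing
#' edges with weight strictly below it are retained as negative edges; it is
#' off by default.
#'
#' @param x Weighted network: adjacency matrix, edgelist data frame, sparse
#'   Matrix, or igraph object.
#' @param upper Scalar threshold, or a function of the adjacency matrix.
#' @param lower Optional scalar (or function) lower threshold for negative
#'   edges.
#' @param narrative Logical; print manuscript-ready text describing the
#'   extraction.
#' @return A [`backbone`][tidy.backbone] tibble (columns `from`, `to`,
#'   `sign`).
#' @examples
#' global_threshold(toy_weighted(), upper = mean)
#' @export
global_threshold <- function(x, upper = mean, lower = NULL, narrative = FALSE) {
  A <- as_adjacency(x)
  thr <- if (is.function(upper)) upper(A) else upper
  if (length(thr) != 1 || !is.numeric(thr) || !is.finite(thr)) {
    abort("`upper` must evaluate to a single finite number.")
  }
  thr_lo <- if (is.null(lower)) NULL else if (is.function(lower)) lower(A) else lower
  if (!is.null(thr_lo) && (length(thr_lo) != 1 || !is.numeric(thr_lo) || !is.finite(thr_lo))) {
    abort("`lower` must evaluate to a single finite number.")
  }
  et <- edge_table(A)
  pos <- et$weight > thr
  neg <- if (is.null(thr_lo)) rep(FALSE, nrow(et)) else et$weight < thr_lo & !pos
  edges <- tibble::tibble(
    from = c(et$from[pos], et$from[neg]),
    to = c(et$to[pos], et$to[neg]),
    sign = c(rep(1L, sum(pos)), rep(-1L, sum(neg)))
  )
  bb <- new_backbone(
    edges,
    nodes = rownames(A),
    model = "global",
    params = list(threshold = thr, lower = thr_lo),
    orig_stats = original_stats(A),
    alpha = NULL, mtc = "none", signed = !is.null(thr_lo),
    network_desc = weighted_desc(A)
  )
  if (narrative) cat(narrative_text(bb))
  bb
}

#' Disparity filter p-values and backbone
#'
#' The disparity filter compares each edge weight to its expectation in a
#' null model where a node's total strength is split uniformly at random
#' across its edges. For an endpoint i with degree \eqn{k_i > 1} and strength
#' \eqn{s_i}, the upper-tail value of edge (i, j) seen from i is
#' \deqn{a_i = (1 - w_{ij}/s_i)^{k_i - 1},}
#' the probability that a uniformly split share exceeds the observed
#' normalized weight. Degree-1 endpoints contribute \eqn{a_i = 1} (their
#' single edge carries the whole strength by construction, so it is never
#' evidence on its own). The edge-level upper-tail p-value is the minimum of
#' the two endpoint values - an edge is kept when it is significant from
#' either side - and the lower tail is its complement (the null is
#' continuous).
#'
#' @param x Weighted network: adjacency matrix, edgelist data frame, sparse
#'   Matrix, or igraph object.
#' @param alpha Significance level in (0, 1), or `NULL` to return the
#'   edgewise p-values themselves for later use with [extract_backbone()].
#' @param signed Logical; two-tailed signed extraction (see
#'   [extract_backbone()]).
#' @param mtc Multiple-test correction, see [adjust_pvalues()].
#' @param narrative Logical; print manuscript-ready text describing the
#'   extraction.
#' @return A [`backbone`][tidy.backbone] tibble, or a `backbone_result`
#'   tibble of p-values when `alpha = NULL`.
#' @examples
#' disparity(toy_weighted(), alpha = 0.05)
#' disparity(toy_weighted(), alpha = NULL)
#' @export
disparity <- function(x, alpha = 0.05, signed = FALSE, mtc = "none",
                      narrative = FALSE) {
  A <- as_adjacency(x)
  maybe_projection_message(A)
  et <- edge_table(A)
  deg <- rowSums(A > 0)
  str <- rowSums(A)
  endpoint_a <- function(node, w) {
    k <- deg[node]
    s <- str[node]
    ifelse(k > 1, (1 - w / s)^(k - 1), 1)
  }
  a_from <- endpoint_a(et$from, et$weight)
  a_to <- endpoint_a(et$to, et$weight)
  et$p_upper <- pmin(a_from, a_to)
  et$p_lower <- 1 - et$p_upper
  res <- new_backbone_result(
    et,
    nodes = rownames(A),
    model = "disparity",
    params = list(),
    orig = A,
    tested = "positive",
    network_desc = weighted_desc(A)
  )
  if (is.null(alpha)) return(res)
  bb <- extract_backbone(res, alpha = alpha, signed = signed, mtc = mtc)
  if (narrative) cat(narrative_text(bb))
  bb
}
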
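# Score / normalize / filter / connect framework for unweighted backbones.
# Edge scores are directional (each endpoint scores its incident edges);
# symmetric scores (jaccard, triangles, random) are simply equal from both
# perspectives. Weighted input is binarized (any positive weight is an edge).

binary_adjacency <- function(x) {
  A <- as_adjacency(x)
  (A > 0) * 1
}

#' Score the edges of an unweighted network
#'
#' Assigns each edge a score from the perspective of each endpoint:
#' * `jaccard`: neighbourhood overlap
#'   \eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|} with open neighbourhoods
#'   (endpoints excluded from their own neighbourhood); symmetric.
#' * `triangles`: the common-neighbour count \eqn{|N(i) \cap N(j)|};
#'   symmetric.
#' * `degree`: the degree of the node at the *other* end; directional.
#' * `random`: one iid uniform(0, 1) draw per edge; symmetric, seeded.
#'
#' @param x Unweighted network (any positive weights are binarized).
#' @param escore Scoring rule.
#' @param seed Optional seed, used only by `escore = "random"`.
#' @return A tibble with one row per (node, incident edge): columns `node`,
#'   `neighbor`, `score`.
#' @export
score_edges <- function(x, escore = c("jaccard", "degree", "triangles", "random"),
                        seed = NULL) {
  escore <- match.arg(escore)
  A <- binary_adjacency(x)
  labs <- rownames(A)
  deg <- rowSums(A)
  et <- edge_table(A)
  i <- match(et$from, labs)
  j <- match(et$to, labs)
  common <- (A %*% A)[cbind(i, j)]
  sym_score <- switch(escore,
    jaccard = {
      uni <- deg[i] + deg[j] - common
      ifelse(uni > 0, common / uni, 0)
    },
    triangles = common,
    random = with_seed_if(seed, runif(nrow(et))),
    degree = NULL
  )
  if (escore == "degree") {
    tibble::tibble(
      node = c(et$from, et$to),
      neighbor = c(et$to, et$from),
      score = unname(c(deg[j], deg[i]))
    )
  } else {
    tibble::tibble(
      node = c(et$from, et$to),
      neighbor = c(et$to, et$from),
      score = rep(unname(sym_score), 2)
    )
  }
}

#' Rank-normalize directional edge scores within each node
#'
#' Replaces each node's incident-edge scores by competition ranks in
#' descending score order: a node's best-scoring edge gets rank 1, and tied
#' scores share the best (minimum) rank. The rank of an edge from one
#' endpoint's perspective is independent of its rank from the other.
#'
#' @param scores A tibble from [score_edges()].
#' @return The tibble with an added `rank` column.
#' @export
rank_normalize <- function(scores) {
  scores %>%
    dplyr::group_by(.data$node) %>%
    dplyr::mutate(rank = rank(-.data$score, ties.method = "min")) %>%
    dplyr::ungroup()
}

#' Degree-dependent rank filter
#'
#' A node of degree d retains its incident edges with rank at most
#' \eqn{\lceil d^s \rceil}; an edge enters the backbone when it is retained
#' from *at least one* endpoint (union semantics), so every non-isolated
#' node keeps at least its top-ranked edge. At `s = 0` each node keeps only
#' its rank-1 edge(s); at `s = 1` all edges survive.
#'
#' @param ranked A tibble from [rank_normalize()].
#' @param s Sparsification exponent in \[0, 1\].
#' @return A tibble of retained undirected edges (`from`, `to`).
#' @export
degree_filter <- function(ranked, s) {
  if (length(s) != 1 || !is.finite(s) || s < 0 || s > 1) {
    abort("`s` must lie in [0, 1].")
  }
  kept <- ranked %>%
    dplyr::group_by(.data$node) %>%
    dplyr::filter(.data$rank <= ceiling(dplyr::n()^s - 1e-9)) %>%
    dplyr::ungroup()
  dedupe_edges(kept$node, kept$neighbor)
}

dedupe_edges <- function(a, b) {
  tibble::tibble(from = pmin(a, b), to = pmax(a, b)) %>%
    dplyr::distinct()
}

#' Edges in the union of maximum-score spanning trees
#'
#' Returns the edges that belong to at least one maximum-score spanning tree
#' of each connected component (equivalently, minimum spanning trees of the
#' distance transform of the similarity scores). An edge qualifies exactly
#' when its endpoints are not connected using strictly higher-scoring edges
#' alone. Used as the "connect" step of [sparsify()]: adding these edges
#' guarantees the backbone has the same connected components as the input.
#'
#' @param scores A tibble from [score_edges()]; directional scores are
#'   symmetrized by taking the larger of the two perspectives.
#' @param x The network the scores came from (used for the node set).
#' @return A tibble of undirected edges (`from`, `to`).
#' @export
umst_edges <- function(scores, x) {
  A <- binary_adjacency(x)
  labs <- rownames(A)
  sym <- scores %>%
    dplyr::mutate(from = pmin(.data$node, .data$neighbor),
                  to = pmax(.data$node, .data$neighbor)) %>%
    dplyr::group_by(.data$from, .data$to) %>%
    dplyr::summarise(score = max(.data$score), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$score))

  parent <- seq_along(labs)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  keep <- logical(nrow(sym))
  i <- 1
  n <- nrow(sym)
  while (i <= n) {
    # process one tie group against the forest of strictly higher edges
    j <- i
    while (j <= n && sym$score[j] == sym$score[i]) j <- j + 1
    grp <- i:(j - 1)
    for (g in grp) {
      keep[g] <- find(match(sym$from[g], labs)) != find(match(sym$to[g], labs))
    }
    for (g in grp) {
      ra <- find(match(sym$from[g], labs))
      rb <- find(match(sym$to[g], labs))
      if (ra != rb) parent[ra] <- rb
    }
    i <- j
  }
  sym[keep, c("from", "to")]
}

#' Sparsify an unweighted network
#'
#' Generic score / normalize / filter / connect backbone model for
#' unweighted networks. Edges are scored ([score_edges()]), optionally
#' rank-normalized per node ([rank_normalize()]), filtered, and optionally
#' re-connected by adding the union of maximum-score spanning trees
#' ([umst_edges()]). Three filters are available:
#' * `degree`: keep each node's \eqn{\lceil d^s \rceil} best-ranked edges
#'   (union semantics; [degree_filter()]);
#' * `threshold`: keep edges with score strictly above `threshold`
#'   (rank at most `threshold` when rank-normalized);
#' * `proportion`: keep the top fraction `proportion` of edges globally by
#'   (symmetrized) score, ties broken by edge label.
#'
#' The presets [sparsify_lspar()] (Jaccard scores: community-preserving) and
#' [sparsify_localdegree()] (neighbour-degree scores: hub-preserving) cover
#' the two named models.
#'
#' @param x Unweighted network (positive weights are binarized).
#' @param escore,seed Passed to [score_edges()].
#' @param normalize `"rank"` or `"none"`.
#' @param filter `"degree"`, `"threshold"`, or `"proportion"`.
#' @param s Sparsification exponent for the degree filter.
#' @param threshold,proportion Parameters of the other two filters.
#' @param umst Logical; add the union-of-maximum-spanning-trees edges.
#' @param narrative Logical; print manuscript-ready text.
#' @return A [`backbone`][tidy.backbone] tibble.
#' @examples
#' g <- sbm_graph(seed = 1)
#' sparsify(g, escore = "jaccard", normalize = "rank", filter = "degree", s = 0.5)
#' @export
sparsify <- function(x, escore = c("jaccard", "degree", "triangles", "random"),
                     normalize = c("rank", "none"),
                     filter = c("degree", "threshold", "proportion"),
                     s = 0.5, threshold = NULL, proportion = NULL,
                     umst = FALSE, seed = NULL, narrative = FALSE,
                     .preset = NULL) {
  escore <- match.arg(escore)
  normalize <- match.arg(normalize)
  filter <- match.arg(filter)
  A <- binary_adjacency(x)
  scores <- score_edges(A, escore = escore, seed = seed)
  ranked <- if (normalize == "rank") rank_normalize(scores) else scores

  edges <- switch(filter,
    degree = {
      if (normalize != "rank") abort("the degree filter needs rank normalization.")
      degree_filter(ranked, s)
    },
    threshold = {
      if (is.null(threshold)) abort("`threshold` must be given for the threshold filter.")
      kept <- if (normalize == "rank") {
        ranked[ranked$rank <= threshold, ]
      } else {
        ranked[ranked$score > threshold, ]
      }
      dedupe_edges(kept$node, kept$neighbor)
    },
    proportion = {
      if (is.null(proportion) || proportion <= 0 || proportion > 1) {
        abort("`proportion` must lie in (0, 1].")
      }
      sym <- scores %>%
        dplyr::mutate(from = pmin(.data$node, .data$neighbor),
                      to = pmax(.data$node, .data$neighbor)) %>%
        dplyr::group_by(.data$from, .data$to) %>%
        dplyr::summarise(score = max(.data$score), .groups = "drop") %>%
        dplyr::arrange(dplyr::desc(.data$score), .data$from, .data$to)
      sym[seq_len(ceiling(proportion * nrow(sym))), c("from", "to")]
    }
  )
  if (umst) {
    edges <- dplyr::distinct(dplyr::bind_rows(edges, umst_edges(scores, A)))
  }
  params <- list(escore = escore, normalize = normalize, filter = filter,
                 s = s, threshold = threshold, proportion = proportion,
                 umst = umst, preset = .preset)
  model <- if (!is.null(.preset)) paste0("sparsify_", .preset) else "sparsify"
  bb <- new_backbone(
    dplyr::mutate(edges, sign = 1L),
    nodes = rownames(A),
    model = model,
    params = params,
    orig_stats = original_stats(A),
    alpha = NULL, mtc = "none", signed = FALSE,
    network_desc = sprintf("an unweighted and undirected unipartite network containing %d nodes", nrow(A)),
    citations = model_citations(model)
  )
  if (narrative) cat(narrative_text(bb))
  bb
}

#' @rdname sparsify
#' @export
sparsify_lspar <- function(x, s = 0.5, narrative = FALSE) {
  sparsify(x, escore = "jaccard", normalize = "rank", filter = "degree",
           s = s, umst = FALSE, narrative = narrative, .preset = "lspar")
}

#' @rdname sparsify
#' @export
sparsify_localdegree <- function(x, s = 0.5, narrative = FALSE) {
  sparsify(x, escore = "degree", normalize = "rank", filter = "degree",
           s = s, umst = FALSE, narrative = narrative, .preset = "localdegree")
}
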
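#' Project a bipartite network onto its agents
#'
#' Builds the weighted agent-by-agent co-occurrence network P = B B' from a
#' binary incidence matrix B: entry \eqn{P_{ij} = \sum_k B_{ik} B_{jk}} counts
#' the artifacts shared by agents i and j. The diagonal is set to zero.
#'
#' @param B Binary incidence matrix (agents in rows, artifacts in columns),
#'   or anything coercible to one (two-column data frame, sparse Matrix,
#'   two-mode igraph).
#' @return A symmetric, labelled adjacency matrix of co-occurrence counts.
#' @examples
#' B <- bipartite_blocks(groups = 2, agents_per = 3, artifacts_per = 4, seed = 1)
#' project(B)
#' @export
project <- function(B) {
  B <- as_incidence(B)
  P <- tcrossprod(B)
  diag(P) <- 0
  dimnames(P) <- list(rownames(B), rownames(B))
  P
}

#' Suggest a backbone model for a network
#'
#' Inspects a network object and reports the detected network type together
#' with the backbone model the package would reach for first. The detection
#' rule is a documented approximation of common practice: a binary
#' rectangular (or binary square non-symmetric) matrix is read as a bipartite
#' incidence structure, a matrix with non-binary weights as a weighted
#' unipartite network, and a binary symmetric matrix as an unweighted
#' unipartite network. A square, symmetric, nonnegative-integer matrix with
#' an off-diagonal entry above 1 looks like a bipartite projection, in which
#' case `projection_warning` is set: backbones of projections are better
#' extracted from the underlying bipartite network with [sdsm()] and friends.
#'
#' @param x A matrix, sparse Matrix, edgelist data frame, or igraph object.
#' @return A one-row tibble with columns `detected_type`
#'   (`"bipartite"`, `"weighted_unipartite"`, `"unweighted_unipartite"`),
#'   `suggested_model`, and `projection_warning`.
#' @examples
#' suggest_model(toy_weighted())
#' @export
suggest_model <- function(x) {
  if (inherits(x, "igraph")) {
    attr_name <- if ("weight" %in% igraph::edge_attr_names(x)) "weight" else NULL
    m <- igraph::as_adjacency_matrix(x, attr = attr_name, sparse = FALSE)
  } else if (inherits(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.data.frame(x)) {
    m <- edgelist_to_adjacency(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    abort("cannot interpret `x` as a network.")
  }
  if (length(m) == 0) abort("empty network.")
  storage.mode(m) <- "double"
  check_finite_nonneg(m, "entries")

  binary <- all(m %in% c(0, 1))
  square <- nrow(m) == ncol(m)
  symmetric <- square && isSymmetric(unname(m), tol = 1e-10)
  off <- if (square) m[row(m) != col(m)] else m

  if (binary && (!square || !symmetric)) {
    type <- "bipartite"; model <- "sdsm"
  } else if (!binary) {
    type <- "weighted_unipartite"; model <- "disparity"
  } else {
    type <- "unweighted_unipartite"; model <- "sparsify_lspar"
  }
  warn_proj <- square && symmetric &&
    all(m == round(m)) && any(off > 1)

  tibble::tibble(
    detected_type = type,
    suggested_model = model,
    projection_warning = warn_proj
  )
}

# Message emitted by weighted models when the input smells like a projection.
maybe_projection_message <- function(A) {
  rep <- suggest_model(A)
  if (rep$projection_warning) {
    inform(paste(
      "This network looks like it could be a bipartite projection.",
      "If so, consider extracting the backbone from the original bipartite",
      "network with a model designed for projections:",
      "sdsm(), fdsm(), fixedfill(), fixedrow(), or fixedcol()."
    ))
  }
  invisible(rep)
}
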
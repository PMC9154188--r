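# Internal coercions between user-facing representations (matrix, sparse
# Matrix, edgelist data frame, igraph) and the canonical containers:
# a labelled symmetric adjacency matrix (unipartite) or a labelled binary
# incidence matrix (bipartite, agents in rows, artifacts in columns).

default_labels <- function(n, prefix = "n") paste0(prefix, seq_len(n))

ensure_dimnames <- function(m, row_prefix = "n", col_prefix = row_prefix) {
  if (is.null(rownames(m))) rownames(m) <- default_labels(nrow(m), row_prefix)
  if (is.null(colnames(m))) colnames(m) <- default_labels(ncol(m), col_prefix)
  m
}

check_finite_nonneg <- function(m, what = "weights") {
  if (!is.numeric(m)) abort(sprintf("%s must be numeric.", what))
  if (any(!is.finite(m))) abort(sprintf("%s must be finite (no NA/NaN/Inf).", what))
  if (any(m < 0)) abort(sprintf("negative %s are not allowed.", what))
  invisible(m)
}

# Edgelist data frame (source, target[, weight]) -> symmetric adjacency.
# Node order follows first appearance, reading each row left to right.
edgelist_to_adjacency <- function(df) {
  if (ncol(df) < 2) abort("an edgelist needs at least source and target columns.")
  src <- as.character(df[[1]])
  tgt <- as.character(df[[2]])
  w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  check_finite_nonneg(w, "edge weights")
  nodes <- unique(as.vector(t(cbind(src, tgt))))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  key <- paste(pmin(src, tgt), pmax(src, tgt))
  if (anyDuplicated(key[src != tgt])) {
    abort("duplicate undirected edges in edgelist.")
  }
  loops <- src == tgt
  if (any(loops)) {
    warn("self-loops dropped (diagonal is defined as zero).")
    src <- src[!loops]; tgt <- tgt[!loops]; w <- w[!loops]
  }
  A[cbind(src, tgt)] <- w
  A[cbind(tgt, src)] <- w
  A
}

#' @keywords internal
as_adjacency <- function(x, arg = "x") {
  if (inherits(x, "igraph")) {
    attr_name <- if ("weight" %in% igraph::edge_attr_names(x)) "weight" else NULL
    m <- igraph::as_adjacency_matrix(x, attr = attr_name, sparse = FALSE)
    if (is.null(rownames(m)) && "name" %in% igraph::vertex_attr_names(x)) {
      rownames(m) <- colnames(m) <- igraph::V(x)$name
    }
  } else if (inherits(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.data.frame(x)) {
    m <- edgelist_to_adjacency(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    abort(sprintf("cannot interpret `%s` as a network (need matrix, Matrix, edgelist data frame, or igraph).", arg))
  }
  if (length(m) == 0) abort("empty network.")
  if (nrow(m) != ncol(m)) {
    abort(sprintf("`%s` is rectangular; a unipartite network needs a square adjacency matrix (use the bipartite models for incidence matrices).", arg))
  }
  storage.mode(m) <- "double"
  check_finite_nonneg(m, "edge weights")
  if (!isSymmetric(unname(m), tol = 1e-10)) {
    abort(sprintf("`%s` must be a symmetric (undirected) adjacency matrix.", arg))
  }
  if (any(diag(m) != 0)) {
    warn("nonzero diagonal set to zero (self-loops are not modelled).")
    diag(m) <- 0
  }
  m <- ensure_dimnames(m)
  colnames(m) <- rownames(m)
  if (anyDuplicated(rownames(m))) abort("node labels must be unique.")
  m
}

#' @keywords internal
as_incidence <- function(x, arg = "B") {
  if (inherits(x, "igraph")) {
    if (!"type" %in% igraph::vertex_attr_names(x)) {
      abort(sprintf("`%s` igraph object has no `type` attribute marking the two modes.", arg))
    }
    m <- igraph::as_biadjacency_matrix(x, sparse = FALSE)
  } else if (inherits(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.data.frame(x)) {
    agents <- unique(as.character(x[[1]]))
    artifacts <- unique(as.character(x[[2]]))
    m <- matrix(0, length(agents), length(artifacts),
                dimnames = list(agents, artifacts))
    v <- if (ncol(x) >= 3) as.numeric(x[[3]]) else rep(1, nrow(x))
    m[cbind(as.character(x[[1]]), as.character(x[[2]]))] <- v
  } else if (is.matrix(x)) {
    m <- x
  } else {
    abort(sprintf("cannot interpret `%s` as a bipartite network.", arg))
  }
  if (length(m) == 0) abort("empty incidence matrix.")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("incidence entries must be finite.")
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary 0/1 incidence matrix.", arg))
  }
  ensure_dimnames(m, "a", "f")
}

# Canonical undirected edge table of a labelled adjacency matrix: one row per
# unordered pair with positive weight, ordered by node position.
edge_table <- function(A, keep_zero = FALSE) {
  labs <- rownames(A)
  idx <- which(upper.tri(A), arr.ind = TRUE)
  w <- A[idx]
  if (!keep_zero) {
    keep <- w > 0
    idx <- idx[keep, , drop = FALSE]
    w <- w[keep]
  }
  tibble::tibble(
    from = labs[idx[, 1]],
    to = labs[idx[, 2]],
    weight = w
  )
}

# Undirected edge identity independent of endpoint order.
edge_key <- function(from, to) paste(pmin(from, to), pmax(from, to), sep = "\r")
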
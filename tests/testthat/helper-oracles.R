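# Independent brute-force oracles used to verify the analytic code paths.

# Pairwise overlap counts by nested loops (projection oracle).
oracle_project <- function(B) {
  r <- nrow(B)
  P <- matrix(0, r, r, dimnames = list(rownames(B), rownames(B)))
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      if (i != j) {
        for (k in seq_len(ncol(B))) P[i, j] <- P[i, j] + B[i, k] * B[j, k]
      }
    }
  }
  P
}

# Poisson-binomial tails by enumerating all 2^n Bernoulli outcomes.
oracle_pb_tail <- function(probs, w) {
  n <- length(probs)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1, function(z) prod(ifelse(z == 1, probs, 1 - probs)))
  s <- rowSums(grid)
  list(p_upper = sum(pr[s >= w]), p_lower = sum(pr[s <= w]))
}

# All binary r x c matrices with exactly the given row and column sums.
margin_class <- function(d, f) {
  r <- length(d); c <- length(f)
  out <- list()
  for (code in 0:(2^(r * c) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(r * c)]
    M <- matrix(bits, r, c)
    if (all(rowSums(M) == d) && all(colSums(M) == f)) out[[length(out) + 1]] <- M
  }
  out
}

# Exact FDSM upper-tail p-values: P(W* >= observed) under the uniform
# distribution over the margin class.
oracle_fdsm_upper <- function(B) {
  cls <- margin_class(rowSums(B), colSums(B))
  P <- tcrossprod(B); ut <- upper.tri(P)
  obs <- P[ut]
  ge <- rep(0, length(obs))
  for (M in cls) {
    w <- tcrossprod(M)[ut]
    ge <- ge + (w >= obs)
  }
  ge / length(cls)
}

# Canonical undirected edge-set signatures (lexicographic endpoint order).
canon_edges <- function(from, to) {
  sort(paste(pmin(from, to), pmax(from, to), sep = "--"))
}

edge_set <- function(bb) canon_edges(bb$from, bb$to)

expect_subset_edges <- function(small, large) {
  expect_true(all(edge_set(small) %in% edge_set(large)))
}

# Construct a minimal backbone_result directly (for inference-level tests).
new_backbone_result_for_test <- function(from, to, weight, p_upper, p_lower) {
  nodes <- sort(unique(c(from, to)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  A[cbind(from, to)] <- weight
  A[cbind(to, from)] <- weight
  netbackbone:::new_backbone_result(
    tibble::tibble(from = from, to = to, weight = weight,
                   p_upper = p_upper, p_lower = p_lower),
    nodes = nodes, model = "disparity", params = list(),
    orig = A, tested = "positive"
  )
}
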
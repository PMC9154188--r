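#' Bipartite configuration model probabilities
#'
#' Fits the maximum-entropy bipartite configuration model (BICM): the
#' distribution over binary incidence matrices that is maximally random
#' subject to matching the observed row sums (agent degrees) and column sums
#' (artifact degrees) *in expectation*. The cell probabilities have the
#' logit-additive form
#' \deqn{Q_{ik} = \frac{x_i y_k}{1 + x_i y_k},}
#' with positive fitness parameters solved by damped fixed-point iteration
#' until every expected margin matches its observed margin within `tol`.
#' Degenerate margins (empty or saturated rows/columns) are peeled off and
#' pre-assigned probability 0 or 1 before solving.
#'
#' This Q matrix is the null model behind [sdsm()].
#'
#' @param B Binary incidence matrix (or coercible).
#' @param tol Maximum absolute margin residual at convergence.
#' @param max_iter Iteration cap; exceeding it is an error naming the worst
#'   residual.
#' @return A matrix of probabilities with the dimensions and dimnames of `B`.
#' @examples
#' B <- bipartite_blocks(groups = 2, agents_per = 4, artifacts_per = 6, seed = 1)
#' Q <- bicm_fit(B)
#' max(abs(rowSums(Q) - rowSums(B)))
#' @export
bicm_fit <- function(B, tol = 1e-8, max_iter = 10000) {
  B <- as_incidence(B)
  r <- nrow(B); c <- ncol(B)
  Q <- matrix(NA_real_, r, c, dimnames = dimnames(B))
  active_r <- rep(TRUE, r)
  active_c <- rep(TRUE, c)

  # Peel degenerate margins iteratively: a row (column) whose effective
  # degree within the active submatrix is 0 or full is deterministic.
  repeat {
    changed <- FALSE
    for (i in which(active_r)) {
      di <- sum(B[i, active_c])
      nc <- sum(active_c)
      if (di == 0 || di == nc) {
        Q[i, active_c] <- as.numeric(di == nc)
        active_r[i] <- FALSE
        changed <- TRUE
      }
    }
    for (k in which(active_c)) {
      fk <- sum(B[active_r, k])
      nr <- sum(active_r)
      if (nr == 0) break
      if (fk == 0 || fk == nr) {
        Q[active_r, k] <- as.numeric(fk == nr)
        active_c[k] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # Cells in inactive rows x inactive columns: fix row-determined values
  # first, then column-determined values for the remainder.
  if (anyNA(Q)) {
    for (i in seq_len(r)) {
      for (k in seq_len(c)) {
        if (is.na(Q[i, k]) && (!active_r[i] || !active_c[k])) {
          Q[i, k] <- B[i, k]
        }
      }
    }
  }

  if (any(active_r) && any(active_c)) {
    sub <- B[active_r, active_c, drop = FALSE]
    d <- rowSums(sub)
    f <- colSums(sub)
    x <- d / sqrt(sum(d))
    y <- f / sqrt(sum(f))
    resid <- Inf
    for (iter in seq_len(max_iter)) {
      xy <- outer(x, y)
      Qs <- xy / (1 + xy)
      # x_i <- d_i / sum_k y_k/(1 + x_i y_k) = d_i x_i / rowSums(Qs)
      x_new <- d * x / rowSums(Qs)
      xy <- outer(x_new, y)
      Qs <- xy / (1 + xy)
      y_new <- f * y / colSums(Qs)
      # geometric damping stabilizes near-saturated margins
      x <- sqrt(x * x_new)
      y <- sqrt(y * y_new)
      xy <- outer(x, y)
      Qs <- xy / (1 + xy)
      resid <- max(abs(rowSums(Qs) - d), abs(colSums(Qs) - f))
      if (resid < tol) break
    }
    if (resid >= tol) {
      abort(sprintf("BICM failed to converge in %d iterations (worst margin residual %.3e).",
                    max_iter, resid))
    }
    Q[active_r, active_c] <- Qs
  }
  Q
}
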
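# Poisson-binomial distribution of a sum of independent Bernoulli variables
# with heterogeneous success probabilities: the null edge-weight distribution
# of the SDSM and fixed-column models.

# Exact PMF over support 0..n by dynamic-programming convolution, O(n^2).
pb_pmf <- function(probs) {
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

# Refined normal approximation with a skewness (second-order, Cornish-Fisher
# style) correction and continuity correction; used above the exact cutoff.
pb_tail_rna <- function(probs, w) {
  mu <- sum(probs)
  s2 <- sum(probs * (1 - probs))
  if (s2 == 0) {
    return(list(p_upper = as.numeric(w <= mu), p_lower = as.numeric(w >= mu)))
  }
  sdv <- sqrt(s2)
  gamma <- sum(probs * (1 - probs) * (1 - 2 * probs)) / s2^1.5
  G <- function(x) {
    val <- pnorm(x) + gamma * (1 - x^2) * dnorm(x) / 6
    pmin(pmax(val, 0), 1)
  }
  list(
    p_upper = 1 - G((w - 0.5 - mu) / sdv),
    p_lower = G((w + 0.5 - mu) / sdv)
  )
}

#' Poisson-binomial tail probabilities
#'
#' Upper- and lower-tail probabilities \eqn{P(W \ge w)} and
#' \eqn{P(W \le w)} for a sum W of independent Bernoulli trials with success
#' probabilities `probs`. Exact by dynamic programming when
#' `length(probs) <= exact_limit`; beyond that a refined normal
#' approximation with skewness and continuity corrections is used.
#'
#' @param probs Vector of success probabilities in \[0, 1\].
#' @param w Integer observed value, `0 <= w <= length(probs)`.
#' @param exact_limit Crossover between exact DP and the approximation.
#' @return A list with `p_upper`, `p_lower`, and `method`
#'   (`"exact"` or `"rna"`). Both tails include the observed value, so
#'   `p_upper + p_lower = 1 + P(W = w)` under the exact method.
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 1)
#' @export
poisson_binomial_tail <- function(probs, w, exact_limit = 1024) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("`probs` must lie in [0, 1].")
  }
  n <- length(probs)
  if (length(w) != 1 || !is.finite(w) || w != round(w) || w < 0 || w > n) {
    abort(sprintf("`w` must be an integer in [0, %d].", n))
  }
  if (n <= exact_limit) {
    pmf <- pb_pmf(probs)
    list(
      p_upper = min(1, sum(pmf[(w + 1):(n + 1)])),
      p_lower = min(1, sum(pmf[1:(w + 1)])),
      method = "exact"
    )
  } else {
    c(pb_tail_rna(probs, w), method = "rna")
  }
}
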
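test_that("poisson_binomial_tail handles point masses and tiny cases", {
  expect_equal(poisson_binomial_tail(rep(0, 4), 0)[c("p_upper", "p_lower")],
               list(p_upper = 1, p_lower = 1))
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 1)$p_upper, 0.75)
  expect_error(poisson_binomial_tail(c(0.5), 2), "integer in")
  expect_error(poisson_binomial_tail(c(1.5), 0), "\\[0, 1\\]")
})

test_that("the DP matches exhaustive enumeration, and the approximation is close", {
  for (seed in 1:3) {
    probs <- withr::with_seed(seed, runif(10))
    for (w in c(0, 3, 7, 10)) {
      got <- poisson_binomial_tail(probs, w)
      want <- oracle_pb_tail(probs, w)
      expect_equal(got$p_upper, want$p_upper, tolerance = 1e-12)
      expect_equal(got$p_lower, want$p_lower, tolerance = 1e-12)
    }
  }
  # refined normal approximation tracks the exact tail when forced on
  probs <- withr::with_seed(9, runif(400, 0.05, 0.6))
  w <- round(sum(probs) + 5)
  exact <- poisson_binomial_tail(probs, w)
  approx <- poisson_binomial_tail(probs, w, exact_limit = 10)
  expect_equal(approx$method, "rna")
  expect_equal(approx$p_upper, exact$p_upper, tolerance = 5e-3)
})

test_that("bicm_fit reproduces margins, including degenerate ones", {
  # saturated incidence: all probabilities one
  expect_equal(unname(bicm_fit(matrix(1, 3, 4))), matrix(1, 3, 4))

  B <- matrix(c(1, 1, 1, 0,
                1, 1, 0, 0,
                1, 0, 1, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  Q <- bicm_fit(B)
  expect_lt(max(abs(rowSums(Q) - rowSums(B))), 1e-7)
  expect_lt(max(abs(colSums(Q) - colSums(B))), 1e-7)
  expect_true(all(Q >= 0 & Q <= 1))
  expect_equal(sum(Q), sum(B), tolerance = 1e-6)
})

test_that("bicm_fit agrees with an independent optimizer on the same constraints", {
  withr::with_seed(5, {
    B <- matrix(rbinom(30, 1, 0.5), 5, 6)
  })
  B[1, ] <- c(1, 1, 1, 0, 0, 1) # ensure non-degenerate margins
  Q <- bicm_fit(B)
  d <- rowSums(B); f <- colSums(B)
  # independent route: minimize squared margin residuals over log-fitnesses
  obj <- function(theta) {
    x <- exp(theta[1:5]); y <- exp(theta[6:11])
    xy <- outer(x, y); Qo <- xy / (1 + xy)
    sum((rowSums(Qo) - d)^2) + sum((colSums(Qo) - f)^2)
  }
  fit <- optim(rep(0, 11), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  x <- exp(fit$par[1:5]); y <- exp(fit$par[6:11])
  Qo <- outer(x, y) / (1 + outer(x, y))
  expect_equal(unname(Q), unname(Qo), tolerance = 1e-4)
})

test_that("sdsm p-values match Monte-Carlo sampling of the null", {
  B <- bipartite_blocks(groups = 2, agents_per = 3, artifacts_per = 4,
                        p_in = 0.8, p_out = 0.2, seed = 31)
  Q <- bicm_fit(B)
  res <- tidy(sdsm(B, alpha = NULL))
  n_mc <- 20000
  withr::with_seed(99, {
    for (row in sample(nrow(res), 4)) {
      i <- match(res$from[row], rownames(B))
      j <- match(res$to[row], rownames(B))
      pij <- Q[i, ] * Q[j, ]
      draws <- matrix(rbinom(n_mc * length(pij), 1, rep(pij, each = n_mc)),
                      nrow = n_mc)
      wstar <- rowSums(draws)
      phat <- mean(wstar >= res$weight[row])
      se <- sqrt(max(phat * (1 - phat), 1e-8) / n_mc)
      expect_lt(abs(phat - res$p_upper[row]), 3 * se + 1e-6)
    }
  })
})

test_that("degenerate incidence matrices give p_upper 1 everywhere", {
  ones <- matrix(1, 4, 6)
  for (fit in list(sdsm(ones, alpha = NULL), fixedrow(ones, alpha = NULL),
                   fixedcol(ones, alpha = NULL), fixedfill(ones, alpha = NULL))) {
    expect_true(all(tidy(fit)$p_upper == 1))
    expect_equal(nrow(suppressMessages(extract_backbone(fit, alpha = 0.5))), 0)
  }
})

test_that("fixedrow matches the column-subset enumeration oracle", {
  # c = 4 artifacts, both agents of degree 2, observed overlap 2
  B <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0), 2, 4, byrow = TRUE)
  r <- tidy(fixedrow(B, alpha = NULL))
  # enumerate row j's choose(4,2) supports against row i fixed
  overlaps <- apply(combn(4, 2), 2, function(cols) length(intersect(cols, c(1, 2))))
  expect_equal(r$p_upper, mean(overlaps >= 2))
  expect_equal(r$p_upper, 1 / 6, tolerance = 1e-12)
  # saturated second row forces full overlap
  B2 <- matrix(c(1, 1, 0, 0,
                 1, 1, 1, 1), 2, 4, byrow = TRUE)
  r2 <- tidy(fixedrow(B2, alpha = NULL))
  expect_equal(r2$p_upper, 1)
  expect_equal(r2$p_lower, 1)
})

test_that("fixedcol matches the placement enumeration oracle", {
  # r = 3 agents, two artifacts of degree 2: pi = 1/3 each, P(W >= 2) = 1/9
  B <- matrix(c(1, 1,
                1, 1,
                0, 0), 3, 2, byrow = TRUE)
  r <- tidy(fixedcol(B, alpha = NULL))
  e12 <- r[r$from == "a1" & r$to == "a2", ]
  # enumerate: each artifact picks 2 of 3 agents uniformly
  subsets <- combn(3, 2, simplify = FALSE)
  both <- vapply(subsets, function(s) all(c(1, 2) %in% s), logical(1))
  p_one <- mean(both)
  expect_equal(p_one, 1 / 3)
  expect_equal(e12$p_upper, p_one^2, tolerance = 1e-12)
  # an artifact with degree <= 1 can never host a co-occurrence
  B3 <- cbind(B, c(1, 0, 0))
  r3 <- tidy(fixedcol(B3, alpha = NULL))
  expect_equal(r3[r3$from == "a1" & r3$to == "a2", ]$p_upper, 1 / 9,
               tolerance = 1e-12)
})

test_that("fixedfill matches the binomial closed form", {
  B <- matrix(c(1, 0,
                0, 1), 2, 2, byrow = TRUE)
  r <- tidy(fixedfill(B, alpha = NULL))
  # q = 1/2; P(W >= 1) with W ~ Binom(2, 1/4)
  expect_equal(r$p_upper[r$weight == 0], 1)
  B2 <- matrix(c(1, 1,
                 0, 0), 2, 2, byrow = TRUE)
  r2 <- tidy(fixedfill(B2, alpha = NULL))
  expect_equal(r2$p_upper, 1) # observed 0
  B3 <- matrix(c(1, 1,
                 1, 0), 2, 2, byrow = TRUE)
  r3 <- tidy(fixedfill(B3, alpha = NULL))
  # q = 3/4, observed overlap 1: P(W >= 1) = 1 - (1 - q^2)^2
  expect_equal(r3$p_upper, 1 - (1 - (3 / 4)^2)^2, tolerance = 1e-12)
})

test_that("every bipartite null satisfies the discrete tail identity", {
  B <- bipartite_blocks(groups = 2, agents_per = 4, artifacts_per = 5,
                        p_in = 0.9, p_out = 0.3, seed = 8)
  for (fit in list(sdsm(B, alpha = NULL), fixedrow(B, alpha = NULL),
                   fixedcol(B, alpha = NULL), fixedfill(B, alpha = NULL),
                   fdsm(B, alpha = NULL, trials = 400, seed = 2))) {
    t <- tidy(fit)
    tot <- t$p_upper + t$p_lower
    expect_true(all(tot >= 1 - 1e-10), label = attr(fit, "model"))
    expect_true(all(tot <= 2 + 1e-10), label = attr(fit, "model"))
  }
})

test_that("increasing the observed weight never increases p_upper", {
  probs <- withr::with_seed(3, runif(12))
  ups <- vapply(0:12, function(w) poisson_binomial_tail(probs, w)$p_upper,
                numeric(1))
  expect_true(all(diff(ups) <= 1e-12))
  d <- c(3, 2); nc <- 5
  hyper_up <- vapply(0:2, function(w) phyper(w - 1, d[1], nc - d[1], d[2],
                                             lower.tail = FALSE), numeric(1))
  expect_true(all(diff(hyper_up) <= 0))
})

test_that("curveball trades preserve margins and are seed-deterministic", {
  B <- bipartite_blocks(groups = 2, agents_per = 5, artifacts_per = 10, seed = 6)
  S1 <- curveball_sample(B, steps = 500, seed = 123)
  S2 <- curveball_sample(B, steps = 500, seed = 123)
  S3 <- curveball_sample(B, steps = 500, seed = 124)
  expect_identical(S1, S2)
  expect_false(identical(S1, S3))
  expect_equal(rowSums(S1), rowSums(B))
  expect_equal(colSums(S1), colSums(B))
  expect_true(all(S1 %in% c(0, 1)))
})

test_that("curveball samples the permutation-margin class uniformly", {
  B <- diag(3)
  dimnames(B) <- list(paste0("a", 1:3), paste0("f", 1:3))
  n_samp <- 6000
  sigs <- character(n_samp)
  for (s in seq_len(n_samp)) {
    M <- curveball_sample(B, steps = 15, seed = 70000 + s)
    sigs[s] <- paste(apply(M, 1, which.max), collapse = "")
  }
  counts <- table(sigs)
  expect_equal(length(counts), 6) # all 3! permutation matrices reached
  chi <- suppressWarnings(chisq.test(counts, p = rep(1 / 6, 6)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("fdsm is reproducible, floored by the add-one rule, and exact for observed zero", {
  B <- bipartite_blocks(groups = 2, agents_per = 3, artifacts_per = 5,
                        p_in = 0.9, p_out = 0.1, seed = 21)
  f1 <- fdsm(B, alpha = NULL, trials = 300, seed = 11)
  f2 <- fdsm(B, alpha = NULL, trials = 300, seed = 11)
  expect_equal(tidy(f1), tidy(f2))
  t <- tidy(f1)
  expect_true(all(t$p_upper >= 1 / 301))
  expect_true(all(t$p_upper[t$weight == 0] == 1))
})

test_that("the automatic trials rule follows the stated confidence-interval bound", {
  n <- netbackbone:::fdsm_auto_trials(0.05)
  expect_lte(qnorm(0.975) * sqrt(0.05 * 0.95 / n), 0.005)
  expect_gt(qnorm(0.975) * sqrt(0.05 * 0.95 / (n - 1)), 0.005)
  expect_error(fdsm(diag(3), alpha = NULL, trials = NULL), "alpha")
})
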
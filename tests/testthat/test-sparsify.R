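triangle <- matrix(c(0, 1, 1,
                     1, 0, 1,
                     1, 1, 0), 3, 3,
                   dimnames = list(c("a", "b", "c"), c("a", "b", "c")))

test_that("edge scores match their definitions on small fixtures", {
  sc <- score_edges(triangle, "jaccard")
  expect_true(all(sc$score == 1 / 3))
  expect_true(all(score_edges(triangle, "triangles")$score == 1))

  path2 <- matrix(c(0, 1, 1, 0), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(score_edges(path2, "jaccard")$score, c(0, 0))

  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star["a", c("b", "c", "d")] <- 1
  star[c("b", "c", "d"), "a"] <- 1
  deg_sc <- score_edges(star, "degree")
  spoke_view <- deg_sc[deg_sc$node == "b" & deg_sc$neighbor == "a", ]
  expect_equal(spoke_view$score, 3)
  hub_view <- deg_sc[deg_sc$node == "a", ]
  expect_true(all(hub_view$score == 1))

  r1 <- score_edges(star, "random", seed = 4)
  r2 <- score_edges(star, "random", seed = 4)
  expect_equal(r1, r2)
  expect_true(all(r1$score >= 0 & r1$score <= 1))
})

test_that("rank normalization uses per-node competition ranks", {
  sc <- tibble::tibble(
    node = c("x", "x", "x", "y"),
    neighbor = c("p", "q", "r", "p"),
    score = c(0.9, 0.2, 0.2, 0.5)
  )
  rk <- rank_normalize(sc)
  expect_equal(rk$rank[rk$node == "x"], c(1, 2, 2))
  expect_equal(rk$rank[rk$node == "y"], 1)

  # asymmetric degrees: the same edge can rank differently from each side
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- A["b", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  A["c", "d"] <- A["d", "c"] <- 1
  A["a", "c"] <- A["c", "a"] <- 1
  rk2 <- rank_normalize(score_edges(A, "degree"))
  cd <- rk2[rk2$node == "c" & rk2$neighbor == "d", ]$rank
  dc <- rk2[rk2$node == "d" & rk2$neighbor == "c", ]$rank
  expect_false(cd == dc)
})

test_that("the degree filter keeps ceil(d^s) edges per node with union semantics", {
  expect_error(degree_filter(rank_normalize(score_edges(triangle, "jaccard")), 2),
               "\\[0, 1\\]")
  # degree 9 node at s = 0.5 keeps its top 3 edges
  star9 <- matrix(0, 10, 10,
                  dimnames = list(paste0("v", 1:10), paste0("v", 1:10)))
  star9["v1", paste0("v", 2:10)] <- 1
  star9[paste0("v", 2:10), "v1"] <- 1
  sc <- tibble::tibble(
    node = c(rep("v1", 9), paste0("v", 2:10)),
    neighbor = c(paste0("v", 2:10), rep("v1", 9)),
    score = c(9:1, rep(1, 9))
  )
  kept <- degree_filter(rank_normalize(sc), 0.5)
  from_hub <- kept[kept$from == "v1" | kept$to == "v1", ]
  # hub keeps ceil(9^0.5) = 3, but every spoke rescues its only edge
  expect_equal(nrow(from_hub), 9)
  hub_ranked <- rank_normalize(sc)
  hub_kept <- hub_ranked[hub_ranked$node == "v1" & hub_ranked$rank <= 3, ]
  expect_equal(nrow(hub_kept), 3)
})

test_that("lspar presets behave at the s extremes", {
  g <- sbm_graph(seed = 10)
  full <- sparsify_lspar(g, s = 1)
  expect_equal(nrow(full), sum(g[upper.tri(g)] > 0))
  sparse <- sparsify_lspar(g, s = 0)
  expect_lt(nrow(sparse), nrow(full))
  # union semantics: no node loses all its edges
  st <- attr(sparse, "stats")
  expect_equal(st$node_reduction_pct, 0)
})

test_that("sparsified edge sets are nested in s and subsets of the input", {
  g <- sbm_graph(seed = 12)
  bbs <- lapply(c(0, 0.3, 0.6, 1), function(s) sparsify_lspar(g, s = s))
  for (k in 1:3) expect_subset_edges(bbs[[k]], bbs[[k + 1]])
  all_edges <- edge_set(sparsify_lspar(g, s = 1))
  for (bb in bbs) expect_true(all(edge_set(bb) %in% all_edges))
})

test_that("umst keeps spanning structure: trees survive, weak cycle edges drop", {
  tree <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tree["a", "b"] <- tree["b", "a"] <- 1
  tree["b", "c"] <- tree["c", "b"] <- 1
  tree["c", "d"] <- tree["d", "c"] <- 1
  sc_tree <- score_edges(tree, "jaccard")
  expect_equal(nrow(umst_edges(sc_tree, tree)), 3)

  cyc <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cyc["a", "b"] <- cyc["b", "a"] <- 1
  cyc["b", "c"] <- cyc["c", "b"] <- 1
  cyc["a", "c"] <- cyc["c", "a"] <- 1
  equal_sc <- tibble::tibble(node = c("a", "b", "a"), neighbor = c("b", "c", "c"),
                             score = c(1, 1, 1))
  expect_equal(nrow(umst_edges(equal_sc, cyc)), 3)
  uneven_sc <- tibble::tibble(node = c("a", "b", "a"), neighbor = c("b", "c", "c"),
                              score = c(1, 1, 0.5))
  kept <- umst_edges(uneven_sc, cyc)
  expect_equal(nrow(kept), 2)
  expect_false("a--c" %in% paste(kept$from, kept$to, sep = "--"))
})

test_that("umst = TRUE preserves the component count", {
  g <- sbm_graph(n = 30, block_sizes = c(15, 15), p_in = 0.4, p_out = 0.05,
                 seed = 77)
  bb <- sparsify(g, escore = "jaccard", normalize = "rank",
                 filter = "degree", s = 0, umst = TRUE)
  comp_in <- igraph::count_components(
    igraph::graph_from_adjacency_matrix(g, mode = "undirected"))
  gb <- igraph::graph_from_data_frame(as.data.frame(bb)[, 1:2],
                                      directed = FALSE,
                                      vertices = attr(bb, "nodes"))
  expect_equal(igraph::count_components(gb), comp_in)
})

test_that("local degree at s = 0 links every node to a top-degree neighbour", {
  pa <- pa_graph(n = 60, m = 3, seed = 42)
  bb <- sparsify_localdegree(pa, s = 0)
  deg <- rowSums(pa)
  es <- cbind(bb$from, bb$to)
  for (v in rownames(pa)) {
    nb <- names(which(pa[v, ] > 0))
    if (!length(nb)) next
    best <- max(deg[nb])
    partners <- c(es[es[, 1] == v, 2], es[es[, 2] == v, 1])
    expect_true(any(deg[intersect(partners, nb)] == best),
                label = sprintf("node %s keeps an edge to a degree-%d neighbour", v, best))
  }
})

test_that("threshold and proportion filters behave and validate", {
  g <- sbm_graph(seed = 15)
  expect_error(sparsify(g, filter = "threshold"), "threshold")
  expect_error(sparsify(g, filter = "proportion", proportion = 0), "proportion")
  half <- sparsify(g, filter = "proportion", proportion = 0.5)
  total <- sum(g[upper.tri(g)] > 0)
  expect_equal(nrow(half), ceiling(0.5 * total))
  rank1 <- sparsify(g, filter = "threshold", threshold = 1)
  expect_equal(edge_set(rank1), edge_set(sparsify_lspar(g, s = 0)))
})
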
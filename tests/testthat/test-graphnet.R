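complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

star_graph <- function(n_leaves) {
  A <- matrix(0L, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  A
}

path3 <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L))

test_that("binarization keeps exactly the top edges with deterministic ties", {
  set.seed(19)
  w <- matrix(0, 19, 19)
  w[upper.tri(w)] <- runif(171)
  w <- w + t(w)
  A <- binarize_top_edges(w, 0.05)
  expect_equal(sum(A) / 2, 9) # ceiling(0.05 * 171)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  # kept edges are precisely the 9 largest weights
  expect_equal(sort(w[upper.tri(w)][A[upper.tri(A)] == 1]),
               sort(w[upper.tri(w)], decreasing = TRUE)[9:1])
  # 5 channels at density 0.2: the 2 largest-weight pairs survive
  w5 <- matrix(0, 5, 5)
  w5[upper.tri(w5)] <- 1:10
  w5 <- w5 + t(w5)
  A5 <- binarize_top_edges(w5, 0.2)
  expect_equal(sum(A5) / 2, 2)
  expect_true(all(w5[upper.tri(w5)][A5[upper.tri(A5)] == 1] %in% c(9, 10)))
  # density -> 1 gives the complete graph
  expect_equal(binarize_top_edges(w5, 0.999), complete_graph(5),
               ignore_attr = TRUE)
  expect_warning(binarize_top_edges(matrix(0.3, 4, 4) - 0.3 * diag(4), 0.5),
                 class = "netsig_degenerate_weights")
  expect_error(binarize_top_edges(w5, 0), class = "netsig_parameter_error")
})

test_that("closed-form fixtures: complete, star, path and disjoint graphs", {
  K5 <- complete_graph(5)
  expect_equal(clustering_coefficient(K5)$C, 1)
  expect_equal(characteristic_path_length(K5), 1)
  expect_equal(global_efficiency(K5), 1)
  expect_equal(betweenness_centrality(K5)$BtwC, 0)
  st <- star_graph(4)
  expect_equal(clustering_coefficient(st)$C, 0)
  expect_equal(betweenness_centrality(st)$per_node[1], 1) # hub carries all paths
  expect_true(all(betweenness_centrality(st)$per_node[-1] == 0))
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)
  # two disjoint edges: reachable pairs only
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(characteristic_path_length(A), 1)
  edgeless <- matrix(0L, 4, 4)
  expect_error(characteristic_path_length(edgeless),
               class = "netsig_undefined_metric")
  expect_equal(global_efficiency(edgeless), 0)
  expect_error(modularity_graph(edgeless), class = "netsig_undefined_metric")
})

test_that("metrics match brute-force oracles on random small graphs", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(4:7, 1)
    A <- random_adjacency(n, p = runif(1, 0.25, 0.7))
    expect_equal(clustering_coefficient(A)$per_node, oracle_clustering(A)$per_node,
                 tolerance = 1e-10)
    lam_o <- oracle_lambda(A)
    if (is.na(lam_o)) {
      expect_error(characteristic_path_length(A), class = "netsig_undefined_metric")
    } else {
      expect_equal(characteristic_path_length(A), lam_o, tolerance = 1e-10)
    }
    expect_equal(global_efficiency(A), oracle_ge(A), tolerance = 1e-10)
    expect_equal(betweenness_centrality(A)$per_node,
                 oracle_betweenness(A)$per_node, tolerance = 1e-10)
    if (sum(A) > 0) {
      memb <- sample(2, n, replace = TRUE)
      expect_equal(modularity_eval(A, memb), oracle_modularity(A, memb),
                   tolerance = 1e-10)
    }
  }
})

test_that("modularity optimizer finds the planted two-clique structure", {
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  A[4, 5] <- A[5, 4] <- 1L
  res <- modularity_graph(A)
  expect_gte(res$Q, 0.35)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(res$Q, oracle_modularity(A, res$membership), tolerance = 1e-12)
  # complete graph as one community has Q exactly 0
  expect_equal(modularity_eval(complete_graph(5), rep(1, 5)), 0)
})

test_that("degree-preserving randomization keeps degrees and kills lattice clustering", {
  g <- igraph::sample_smallworld(1, 20, 2, 0) # ring lattice k = 4
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(A) <- "integer"
  c_drop <- vapply(1:20, function(s) {
    R <- random_reference(A, seed = s)
    expect_identical(rowSums(R), rowSums(A))
    clustering_coefficient(R)$C
  }, numeric(1))
  expect_lt(mean(c_drop), 0.5 * clustering_coefficient(A)$C)
  expect_identical(random_reference(A, seed = 3), random_reference(A, seed = 3))
  # degenerate: too few edges returns the input with a warning
  tiny <- matrix(0L, 3, 3); tiny[1, 2] <- tiny[2, 1] <- 1L
  expect_warning(out <- random_reference(tiny), class = "netsig_degenerate_graph")
  expect_identical(out, tiny)
})

test_that("small-world index separates rewired lattices from their nulls", {
  g <- igraph::sample_smallworld(1, 20, 2, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(A) <- "integer"
  swis <- vapply(1:10, function(s) small_world_index(A, n_null = 20, seed = s),
                 numeric(1))
  expect_gt(mean(swis), 1)
  # complete graph: nulls are the graph itself
  expect_equal(small_world_index(complete_graph(6)), 1)
  # a random reference of a random graph is its own null (mean over draws;
  # single draws fluctuate widely at this size)
  set.seed(22)
  base <- binarize_top_edges({
    w <- matrix(0, 12, 12); w[upper.tri(w)] <- runif(66); w + t(w)
  }, 0.3)
  self_null <- vapply(1:8, function(s) {
    small_world_index(random_reference(base, seed = 100 + s),
                      n_null = 20, seed = s)
  }, numeric(1))
  expect_equal(mean(self_null), 1, tolerance = 0.25)
  expect_error(small_world_index(matrix(0L, 5, 5)),
               class = "netsig_undefined_metric")
})

test_that("metrics are invariant under node relabeling and monotone in edges", {
  set.seed(23)
  A <- random_adjacency(7, 0.45)
  perm <- sample(7)
  Ap <- A[perm, perm]
  expect_equal(global_efficiency(A), global_efficiency(Ap))
  expect_equal(clustering_coefficient(A)$C, clustering_coefficient(Ap)$C)
  expect_equal(betweenness_centrality(A)$BtwC, betweenness_centrality(Ap)$BtwC)
  expect_equal(sort(betweenness_centrality(A)$per_node),
               sort(betweenness_centrality(Ap)$per_node))
  # adding an edge never decreases efficiency
  for (rep in 1:20) {
    B <- random_adjacency(6, 0.3)
    off <- which(B == 0 & upper.tri(B), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    B2 <- B
    B2[pick[1], pick[2]] <- B2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(B2), global_efficiency(B))
  }
})

test_that("graph_metrics returns the six metrics per band", {
  set.seed(24)
  mats <- list(delta = {
    w <- matrix(0, 19, 19); w[upper.tri(w)] <- runif(171); w + t(w)
  })
  gm <- graph_metrics(mats, seed = 2)
  expect_equal(gm$band, "delta")
  expect_true(all(c("Q", "swi", "btwc", "ge", "clustering", "lambda") %in% names(gm)))
  expect_true(gm$ge >= 0 && gm$ge <= 1)
  expect_true(gm$btwc >= 0 && gm$btwc <= 1)
  expect_true(is.na(gm$lambda) || gm$lambda >= 1)
})
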
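test_that("knn sets match a brute-force distance sort", {
  set.seed(1)
  emb <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  ns <- knn_sets(emb, k = 3, include_self = FALSE)
  D <- as.matrix(dist(emb))
  for (i in 1:10) {
    d <- D[i, -i]
    expected <- sort(as.integer(
      names(sort(d))[1:3] |> sub(pattern = "c", replacement = "")))
    expect_equal(ns$sets[[i]], expected)
  }
})

test_that("the middle of three collinear points picks the closer endpoint", {
  emb <- cbind(c(0, 1, 3), 0)
  rownames(emb) <- c("a", "b", "c")
  ns <- knn_sets(emb, k = 1, include_self = FALSE)
  expect_equal(ns$sets[[2]], 1L)
})

test_that("duplicate coordinates break ties by index", {
  emb <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 5))
  rownames(emb) <- paste0("c", 1:4)
  ns <- knn_sets(emb, k = 1, include_self = FALSE)
  expect_equal(ns$sets[[3]], 1L)     # lowest index among equidistant
  ns2 <- knn_sets(emb, k = 2, include_self = TRUE)
  expect_equal(ns2$sets[[1]], c(1L, 2L, 3L))
})

test_that("knn rejects invalid k", {
  emb <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("c", 1:5), NULL))
  expect_error(knn_sets(emb, k = 0), "positive")
  expect_error(knn_sets(emb, k = 5), "smaller")
})

test_that("Jaccard weights follow set arithmetic", {
  sets <- structure(list(
    sets = list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(5L, 6L, 7L), c(1L, 2L, 3L),
                c(5L, 6L, 7L)),
    ids = paste0("c", 1:5), k = 3, include_self = FALSE),
    class = "neighbor_sets")
  g <- snn_jaccard(sets, prune_below = 0)
  expect_equal(g["c1", "c2"], 2 / 4)   # {a,b,c} vs {b,c,d}
  expect_equal(g["c1", "c4"], 1)       # identical sets
  expect_equal(g["c1", "c3"], 0)       # disjoint -> no edge
  expect_equal(g["c3", "c5"], 1)
  expect_true(Matrix::isSymmetric(g))
  expect_true(all(Matrix::diag(g) == 0))
})

test_that("pruning drops weak edges", {
  sets <- structure(list(
    sets = list(1:10, c(1L, 11:19), 2:11),
    ids = paste0("c", 1:3), k = 10, include_self = FALSE),
    class = "neighbor_sets")
  g0 <- snn_jaccard(sets, prune_below = 0)
  expect_equal(g0["c1", "c2"], 1 / 19)
  g <- snn_jaccard(sets, prune_below = 1 / 15)
  expect_equal(g["c1", "c2"], 0)
  expect_gt(g["c1", "c3"], 0)
})

test_that("modularity matches exhaustive brute force on small graphs", {
  set.seed(42)
  n_checked <- 0
  for (s in 1:12) {
    n <- sample(4:7, 1)
    A <- random_graph(n, p = 0.6)
    if (sum(A) == 0) next
    for (part in all_partitions(n)) {
      expect_lt(abs(modularity_q(A, part) - brute_modularity(A, part)),
                1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
})

test_that("trivial partition identities hold", {
  A <- random_graph(6, p = 0.7)
  expect_equal(modularity_q(A, rep(1, 6)), 0, tolerance = 1e-12)
  # two-node single-edge graph, singleton communities
  A2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  expect_equal(modularity_q(A2, c(1, 2)), -0.5)
})

test_that("modularity is invariant to uniform weight rescaling", {
  set.seed(3)
  A <- random_graph(8, p = 0.5)
  part <- c(1, 1, 1, 2, 2, 2, 3, 3)
  expect_equal(modularity_q(A, part), modularity_q(A * 7.3, part),
               tolerance = 1e-12)
})

test_that("the gain formula equals the modularity difference for all moves", {
  set.seed(9)
  for (rep in 1:3) {
    A <- random_graph(12, p = 0.4)
    membership <- sample(1:4, 12, replace = TRUE)
    for (node in 1:12) {
      # isolate the node in its own fresh community
      iso <- membership
      iso[node] <- 99L
      base_q <- modularity_q(A, iso)
      for (target in unique(membership[-node])) {
        moved <- iso
        moved[node] <- target
        for (gamma in c(1, 0.5)) {
          dq <- modularity_gain(A, iso, node, target, resolution = gamma)
          expect_lt(abs(dq - (modularity_q(A, moved, gamma) -
                                modularity_q(A, iso, gamma))),
                    1e-12)
        }
      }
    }
  }
})

test_that("gain of joining a singleton community already occupied is zero", {
  A <- random_graph(5, p = 0.9)
  membership <- c(1, 2, 3, 4, 5)
  # node 2 alone in community 2: joining "2" again changes nothing
  expect_equal(modularity_gain(A, membership, 2, 2), 0)
})

test_that("gain signs separate planted cliques", {
  # two 4-cliques joined by one weak edge
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 0.1
  A <- Matrix::Matrix(A, sparse = TRUE)
  membership <- c(9, 1, 1, 1, 2, 2, 2, 2)   # node 1 isolated
  expect_gt(modularity_gain(A, membership, 1, 1), 0)
  expect_lt(modularity_gain(A, membership, 1, 2), 0)
})

test_that("louvain finds the exhaustively optimal two-triangle partition", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  A[3, 4] <- A[4, 3] <- 0.2
  A <- Matrix::Matrix(A, sparse = TRUE)
  part <- louvain(A, resolution = 1, seed = 2)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(unname(part$membership[1:3]),
               rep(part$membership[[1]], 3))
  best <- max(vapply(all_partitions(6),
                     function(p) brute_modularity(A, p), 0))
  expect_equal(part$modularity, best, tolerance = 1e-12)
})

test_that("disjoint cliques map to one community each", {
  A <- matrix(0, 9, 9)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; A[7:9, 7:9] <- 1; diag(A) <- 0
  A <- Matrix::Matrix(A, sparse = TRUE)
  part <- louvain(A, resolution = 1, seed = 5)
  expect_equal(length(unique(part$membership)), 3)
  for (block in list(1:3, 4:6, 7:9))
    expect_equal(length(unique(part$membership[block])), 1)
})

test_that("louvain labels are contiguous, 0-based, size-ordered", {
  g <- generate_planted_partition_graph(c(30, 15, 8), 0.9, 0.02, seed = 3)
  part <- louvain(g$graph, resolution = 1, seed = 3)
  labs <- part$membership
  expect_equal(sort(unique(unname(labs))), 0:(length(unique(labs)) - 1))
  sizes <- as.integer(table(labs)[as.character(0:(length(unique(labs)) - 1))])
  expect_true(all(diff(sizes) <= 0))
  expect_true(part$modularity >= 0)
  expect_true(part$modularity <= 1)
})

test_that("louvain matches igraph's modularity optimum on planted graphs", {
  # independent-implementation cross-check
  for (s in 1:3) {
    g <- generate_planted_partition_graph(c(15, 15), 0.8, 0.05, seed = s)
    mine <- louvain(g$graph, resolution = 1, seed = s)
    ig <- igraph::graph_from_adjacency_matrix(g$graph, mode = "undirected",
                                              weighted = TRUE)
    ref <- igraph::cluster_louvain(ig)
    expect_equal(mine$modularity,
                 igraph::modularity(ig, igraph::membership(ref)),
                 tolerance = 0.02)
  }
})

test_that("louvain is near the exhaustive optimum on tiny random graphs", {
  set.seed(77)
  worst <- 0
  for (s in 1:50) {
    n <- sample(5:9, 1)
    A <- random_graph(n, p = 0.5)
    if (sum(A) == 0) next
    part <- louvain(A, resolution = 1, seed = s)
    best <- max(vapply(all_partitions(n),
                       function(p) brute_modularity(A, p), 0))
    worst <- max(worst, best - part$modularity)
  }
  expect_lte(worst, 0.02)
})

test_that("aggregation conserves weight and modularity exactly", {
  set.seed(11)
  for (rep in 1:5) {
    A <- random_graph(10, p = 0.5)
    if (sum(A) == 0) next
    part <- sample(1:3, 10, replace = TRUE)
    agg <- aggregate_graph(A, part)
    expect_equal(sum(agg), sum(A), tolerance = 1e-12)
    expect_equal(modularity_q(agg, rownames(agg)),
                 modularity_q(A, part), tolerance = 1e-12)
  }
  # singleton communities give back an isomorphic graph
  A <- random_graph(6, 0.6)
  agg <- aggregate_graph(A, 1:6)
  expect_equal(unname(as.matrix(agg)), unname(as.matrix(A)))
})

test_that("aggregate weights match hand-summed blocks", {
  A <- Matrix::sparseMatrix(i = c(1, 2, 1, 3, 2, 4, 3, 4),
                            j = c(2, 1, 3, 1, 4, 2, 4, 3),
                            x = c(2, 2, 1, 1, 3, 3, 5, 5), dims = c(4, 4))
  agg <- aggregate_graph(A, c("x", "x", "y", "y"))
  expect_equal(agg["x", "x"], 4)   # 2*2 internal edge weight, ordered pairs
  expect_equal(agg["y", "y"], 10)
  expect_equal(agg["x", "y"], 4)   # edges 1-3 (1) and 2-4 (3)
})
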
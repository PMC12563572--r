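star_graph <- function() {
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- A[2:5, 1] <- 1
  A
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

test_that("nodal statistics on canonical small graphs", {
  pos <- cbind(c(0, 1, 0, -1, 0), c(0, 0, 1, 0, -1)) * 100
  ns <- nodal_statistics(star_graph(), distance_um = position_distances(pos))
  expect_equal(ns$degree, c(4, 1, 1, 1, 1))
  expect_equal(ns$clustering, rep(0, 5))
  # centre lies on all 6 leaf pairs' shortest paths
  expect_equal(ns$betweenness, c(6, 0, 0, 0, 0))

  tri <- matrix(1, 3, 3) - diag(3)
  ns_t <- nodal_statistics(tri, distance_um = matrix(1, 3, 3) - diag(3))
  expect_equal(ns_t$clustering, rep(1, 3))
  expect_equal(ns_t$betweenness, rep(0, 3))
})

test_that("matching index on the 4-path matches set computation", {
  A <- path_graph(4)
  M <- matching_matrix(A)
  expect_equal(M[1, 3], 0.5)   # shared {2} over union {2, 4}
  expect_equal(M[2, 3], 0)     # neighbourhoods excluding each other: {1},{4}
  expect_equal(M, t(M))
  # identical neighbourhoods excluding each other -> 1
  B <- star_graph()
  MB <- matching_matrix(B)
  expect_equal(MB[2, 3], 1)
})

test_that("graph statistics agree with brute-force oracles on small graphs", {
  set.seed(21)
  for (r in 1:60) {
    n <- sample(3:7, 1)
    A <- random_small_graph(n)
    D <- position_distances(random_positions(n))
    ns <- nodal_statistics(A, distance_um = D)
    expect_equal(ns$betweenness, oracle_betweenness(A), tolerance = 1e-12)
    expect_equal(ns$efficiency, oracle_nodal_efficiency(A), tolerance = 1e-12)
    expect_equal(ns$clustering, oracle_clustering(A), tolerance = 1e-12)
    expect_equal(matching_matrix(A), oracle_matching(A), tolerance = 1e-12)
    memb <- sample(1:2, n, replace = TRUE)
    if (sum(A) > 0)
      expect_equal(modularity_at_partition(A, memb),
                   oracle_modularity(A, memb), tolerance = 1e-12)
  }
})

test_that("statistics are equivariant under node relabeling", {
  set.seed(22)
  A <- random_small_graph(7, 0.4)
  D <- position_distances(random_positions(7))
  perm <- sample(7)
  ns1 <- nodal_statistics(A, distance_um = D)
  ns2 <- nodal_statistics(A[perm, perm], distance_um = D[perm, perm])
  for (col in names(ns1))
    expect_equal(ns2[[col]], ns1[[col]][perm], tolerance = 1e-12)
})

test_that("global statistics: complete graph and degree bookkeeping", {
  K10 <- matrix(1, 10, 10) - diag(10)
  gs <- global_statistics(K10, n_null = 20, seed = 1, n_louvain = 5)
  expect_equal(gs$density, 1)
  expect_equal(gs$global_efficiency, 1)
  expect_equal(gs$char_path_length, 1)
  set.seed(23)
  A <- random_small_graph(12, 0.3)
  ns <- nodal_statistics(A, distance_um = position_distances(random_positions(12)))
  expect_equal(sum(ns$degree), sum(A))
})

test_that("small-worldness exceeds 1 for a rewired ring lattice", {
  g <- igraph::sample_smallworld(1, 100, 2, 0.1)
  A <- unname(as.matrix(igraph::as_adjacency_matrix(g)))
  gs <- global_statistics(A, n_null = 50, seed = 4, n_louvain = 5)
  expect_gt(gs$small_worldness, 1)
})

test_that("modularity of two disjoint cliques matches exhaustive 2-partitions", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1
  diag(A) <- 0
  memb_true <- rep(1:2, each = 5)
  q_true <- modularity_at_partition(A, memb_true)
  # exhaustive search over all 2-partitions using the independent oracle
  best <- -Inf
  for (code in 0:(2^10 - 1)) {
    memb <- as.integer(intToBits(code))[1:10]
    best <- max(best, oracle_modularity(A, memb))
  }
  expect_equal(q_true, best, tolerance = 1e-12)
  expect_equal(q_true, 0.5)
  # Louvain-based Q finds the planted split
  gs <- global_statistics(A, n_null = 10, seed = 2, n_louvain = 5)
  expect_equal(gs$modularity, 0.5, tolerance = 1e-12)
})

test_that("participation coefficient separates intra- from inter-module hubs", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  A[3, 4] <- A[4, 3] <- 1
  memb <- rep(1:2, each = 3)
  p <- participation_coefficient(A, memb)
  expect_equal(p[1], 0)          # purely within-module
  expect_gt(p[3], 0)             # bridge node
  expect_true(all(p >= 0 & p <= 1))
})

test_that("non-symmetric adjacency is rejected", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  expect_error(nodal_statistics(A, distance_um = matrix(1, 3, 3)), "symmetric")
})
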
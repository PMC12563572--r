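test_that("wiring values reproduce direct set computations", {
  A0 <- matrix(0, 4, 4)
  expect_equal(wiring_value(A0, "deg_avg"), matrix(0, 4, 4))
  expect_true(all(wiring_value(A0, "spatial")[upper.tri(A0)] == 1))
  P4 <- matrix(0, 4, 4)
  for (i in 1:3) P4[i, i + 1] <- P4[i + 1, i] <- 1
  expect_equal(wiring_value(P4, "matching")[1, 3], 0.5)
  expect_equal(wiring_value(P4, "neighbors")[1, 3], 1)
  expect_error(wiring_value(A0, "not_a_rule"))
  # rule bookkeeping
  expect_length(gnm_rules(), 13)
  expect_equal(gnm_rule_group("matching"), "homophily")
  expect_equal(gnm_rule_group("clu_prod"), "clustering")
})

test_that("probability scores follow the wiring equation", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  K <- matrix(1, 3, 3)
  eps <- 1e-6
  P <- probability_scores(D, K, eta = -1, gamma = 1, epsilon = eps)
  expect_equal(P[1, 2], 1 * (1 + eps))
  expect_equal(P[1, 3], 0.5 * (1 + eps))
  expect_equal(diag(P), rep(0, 3))
  # eta = gamma = 0: all off-diagonal scores equal
  P0 <- probability_scores(D, K, 0, 0)
  expect_equal(length(unique(P0[row(P0) != col(P0)])), 1L)
  # power-law scale covariance: doubling D with eta = -1 halves scores
  P2 <- probability_scores(2 * D, K, -1, 1, eps)
  expect_equal(P2[row(P2) != col(P2)], P[row(P) != col(P)] / 2)
})

test_that("growth produces exactly m symmetric edges, deterministically", {
  set.seed(31)
  D <- position_distances(random_positions(30))
  cfg <- gnm_config("matching", -2, 2, 60, seed = 5)
  tr1 <- grow_network(D, cfg)
  tr2 <- grow_network(D, cfg)
  expect_identical(tr1$edge_order, tr2$edge_order)
  A <- tr1$adjacency
  expect_equal(sum(A) / 2, 60)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0L, 30))
  expect_equal(nrow(tr1$edge_order), 60)
  expect_false(any(duplicated(tr1$edge_order)))
  # m = 0: empty graph, empty trace
  tr0 <- grow_network(D, gnm_config("spatial", 0, 0, 0, seed = 1))
  expect_equal(sum(tr0$adjacency), 0)
  expect_equal(nrow(tr0$edge_order), 0)
})

test_that("eta=gamma=0 growth is indistinguishable from uniform random graphs", {
  set.seed(32)
  D <- position_distances(random_positions(20))
  deg_gnm <- unlist(lapply(1:100, function(s) {
    rowSums(grow_network(D, gnm_config("matching", 0, 0, 40, seed = s),
                         record_trace = FALSE)$adjacency)
  }))
  deg_er <- unlist(lapply(1:100, function(s) {
    set.seed(1000 + s)
    igraph::degree(igraph::sample_gnm(20, 40))
  }))
  p <- suppressWarnings(stats::ks.test(deg_gnm, deg_er))$p.value
  expect_gt(p, 0.01)
})

test_that("extreme negative eta picks the globally closest pair", {
  set.seed(33)
  pos <- random_positions(10)
  D <- position_distances(pos)
  closest <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  hits <- vapply(1:200, function(s) {
    e <- grow_network(D, gnm_config("spatial", -50, 0, 1, seed = s),
                      record_trace = FALSE)$edge_order
    setequal(e[1, ], closest)
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("stronger distance penalties shorten total edge length", {
  set.seed(34)
  D <- position_distances(random_positions(40))
  mean_len <- function(eta) {
    mean(vapply(1:30, function(s) {
      A <- grow_network(D, gnm_config("spatial", eta, 0, 80, seed = s),
                        record_trace = FALSE)$adjacency
      sum(A * D) / 2 / 80
    }, 0))
  }
  l0 <- mean_len(0); l1 <- mean_len(-1); l3 <- mean_len(-3)
  expect_gt(l0, l1)
  expect_gt(l1, l3)
})

test_that("the matching rule enacts its own statistic", {
  set.seed(35)
  D <- position_distances(random_positions(40))
  mm <- function(rule) {
    mean(vapply(1:20, function(s) {
      A <- grow_network(D, gnm_config(rule, -1, 2, 80, seed = s),
                        record_trace = FALSE)$adjacency
      M <- matching_matrix(A)
      mean(M[upper.tri(M)])
    }, 0))
  }
  expect_gt(mm("matching"), mm("spatial"))
})

test_that("growth trace snapshots cover completion and rebuild adjacency", {
  set.seed(36)
  D <- position_distances(random_positions(25))
  tr <- grow_network(D, gnm_config("deg_avg", -1, 1, 50, seed = 2,
                                   snapshot_interval = 0.1))
  expect_equal(length(tr$p_snapshots), 10)
  expect_equal(max(tr$snapshot_fractions), 1)
  # snapshot k holds scores over pairs still unconnected at that point
  expect_equal(length(tr$p_snapshots[[10]]), 25 * 24 / 2 - 50)
  expect_equal(adjacency_at_fraction(tr, 1), tr$adjacency,
               ignore_attr = TRUE)
  A_half <- adjacency_at_fraction(tr, 0.5)
  expect_equal(sum(A_half) / 2, 25)
})

test_that("degenerate exponentiation is reported, not silently absorbed", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(grow_network(matrix(0, 2, 2),
                            gnm_config("spatial", -1, 0, 1, seed = 1)),
               "positive")
})
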
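test_that("KS distance reproduces hand-evaluated cases", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_statistic(1:4, 3:6), 0.5)
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
  # agreement with the naive double-loop oracle on random samples
  set.seed(41)
  for (r in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), mean = 0.5)
    expect_equal(ks_statistic(x, y), oracle_ks(x, y), tolerance = 1e-12)
  }
})

test_that("energy identities hold and components never exceed the maximum", {
  set.seed(42)
  net <- grow_fixture_network("matching", -2, 2, 30, 80, seed = 6)
  e0 <- energy(net, net$adjacency)
  expect_equal(e0$energy, 0)
  for (s in 1:5) {
    A <- grow_network(net$distance_um,
                      gnm_config("spatial", -1, 0, 80, seed = s),
                      record_trace = FALSE)$adjacency
    e <- energy(net, A)
    ks <- c(e$ks_degree, e$ks_clustering, e$ks_betweenness, e$ks_edge_length)
    expect_true(all(ks <= e$energy + 1e-15))
    expect_true(e$energy >= 0 && e$energy <= 1)
    expect_equal(e$energy, max(ks))
  }
  # mismatched edge counts are flagged but still scored
  A_small <- grow_network(net$distance_um,
                          gnm_config("spatial", -1, 0, 40, seed = 1),
                          record_trace = FALSE)$adjacency
  expect_warning(energy(net, A_small), "edge count")
})

test_that("energy of a 5-node fixture equals a first-principles recomputation", {
  pos <- cbind(c(0, 100, 200, 50, 150), c(0, 50, 0, 150, 150))
  A_obs <- matrix(0, 5, 5)
  A_obs[1, 2] <- A_obs[2, 3] <- A_obs[3, 4] <- A_obs[1, 4] <- 1
  A_obs <- A_obs + t(A_obs)
  A_sim <- matrix(0, 5, 5)
  A_sim[1, 2] <- A_sim[2, 5] <- A_sim[4, 5] <- A_sim[2, 3] <- 1
  A_sim <- A_sim + t(A_sim)
  net <- functional_network(A_obs, pos)
  e <- energy(net, A_sim)
  o <- oracle_energy(A_obs, A_sim, net$distance_um)
  expect_equal(e$energy, o$energy, tolerance = 1e-12)
  expect_equal(c(e$ks_degree, e$ks_clustering, e$ks_betweenness,
                 e$ks_edge_length), o$components, tolerance = 1e-12)
})

test_that("topological fingerprints: identity, symmetry, norm scale", {
  set.seed(43)
  a <- grow_fixture_network("matching", -2, 2, 25, 60, seed = 7)
  b <- grow_fixture_network("spatial", -3, 0, 25, 60, seed = 8)
  TA <- tf_matrix(a); TB <- tf_matrix(b)
  expect_equal(dim(TA), c(6, 6))
  expect_equal(unclass(TA), t(unclass(TA)), tolerance = 1e-12)
  expect_equal(diag(TA), rep(1, 6), ignore_attr = TRUE)
  expect_equal(tf_dissimilarity(TA, TA), 0)
  expect_equal(tf_dissimilarity(TA, TB), tf_dissimilarity(TB, TA))
  expect_gte(tf_dissimilarity(TA, TB), 0)
  # a full 6x6 difference of ones has Frobenius norm 6
  expect_equal(tf_dissimilarity(matrix(1, 6, 6), matrix(0, 6, 6)), 6)
  # constant statistic: undefined entries imputed as 0 with a message
  A_ring <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; A_ring[i, j] <- A_ring[j, i] <- 1 }
  T_ring <- tf_matrix(functional_network(A_ring, cbind(1:5, (1:5)^2)))
  expect_true(any(is.na(unclass(T_ring))))
  expect_message(d <- tf_dissimilarity(T_ring, TA), "imputed")
  expect_true(is.finite(d))
})

test_that("p_rank handles outliers and degenerate ties as designed", {
  sims <- lapply(1:99, function(i) rnorm(30))
  # observation far outside the simulation support
  expect_lte(prank(rnorm(30, mean = 50), sims), 2 / 100)
  # observation identical to every simulation: midrank convention gives 1
  same <- lapply(1:99, function(i) c(1, 2, 3))
  expect_equal(prank(c(1, 2, 3), same), 1)
  expect_error(prank(rnorm(10), sims[1:50]), "expected 99")
})

test_that("p_rank is approximately uniform under exchangeability", {
  set.seed(44)
  pr <- vapply(1:200, function(r) {
    sims <- lapply(1:99, function(i) rnorm(15))
    prank(rnorm(15), sims)
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(pr, "punif"))$p.value, 0.01)
})

test_that("trajectory decomposition is exact at completion and monotone in reach", {
  set.seed(45)
  net <- grow_fixture_network("matching", -2, 2, 40, 120, seed = 9)
  tr <- attr(net, "trace")
  tr <- grow_network(net$distance_um, tr$config, record_trace = TRUE)
  td <- trajectory_decomposition(tr, fractions = c(0.25, 0.5, 1),
                                 n_louvain = 5, seed = 1)
  expect_equal(td$n_edges, c(30, 60, 120))
  gs_final <- global_statistics(tr$adjacency, n_null = 5, seed = 1,
                                n_louvain = 5)
  expect_equal(td$global_efficiency[3], gs_final$global_efficiency,
               tolerance = 1e-12)
  expect_equal(td$modularity[3], gs_final$modularity, tolerance = 1e-12)
  # efficiency cannot decrease as nested edges accumulate
  expect_true(all(diff(td$global_efficiency) >= -1e-12))
  expect_error(trajectory_decomposition(tr, fractions = 1.5), "fractions")
})

test_that("probability-score summaries behave on known distributions", {
  fake_trace <- function(scores) {
    structure(list(p_snapshots = list(scores), snapshot_fractions = 1,
                   edge_order = matrix(integer(0), 0, 2),
                   adjacency = matrix(0, 2, 2)),
              class = "growth_trace")
  }
  # uniform scores: flat histogram, median ~ mean, tiny uniform excess
  u <- seq(1e-6, 1, length.out = 5000)
  su <- pij_distribution_summary(fake_trace(u))
  expect_lt(su$uniform_excess, 0.02)
  expect_equal(su$median_score, su$mean_score, tolerance = 0.01)
  # lognormal scores: right-skewed, median < mean, large uniform excess
  set.seed(46)
  ln <- rlnorm(5000, 0, 1)
  sl <- pij_distribution_summary(fake_trace(ln))
  expect_lt(sl$median_score, sl$mean_score)
  expect_gt(sl$uniform_excess, su$uniform_excess)
  expect_equal(sum(su$density), 1, tolerance = 1e-12)
  expect_error(pij_distribution_summary(list()), "no traces")
})
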
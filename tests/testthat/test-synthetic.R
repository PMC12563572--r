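test_that("generation is deterministic under the seed", {
  p <- small_culture(seed = 101)
  g1 <- generate_culture(p)
  g2 <- generate_culture(p)
  expect_identical(g1$set$spikes, g2$set$spikes)
  expect_identical(g1$set$positions, g2$set$positions)
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_culture(small_culture(seed = 102))
  expect_false(identical(g1$set$spikes, g3$set$spikes))
})

test_that("parameter validation rejects degenerate cultures", {
  expect_error(culture_params(n_units = 1), "n_units")
  expect_error(culture_params(duration_s = 0), "duration")
  expect_error(culture_params(participation_base = 1.5), "probabilities")
  expect_error(culture_params(dev_stage = 0), "dev_stage")
})

test_that("pure Poisson limit: counts in the central 99.9% range", {
  p <- culture_params(n_units = 30, duration_s = 100, burst_rate_hz = 0,
                      base_rate_lognorm_mu = 0, base_rate_lognorm_sigma = 0,
                      coupling_within = 0, coupling_between = 0, seed = 5)
  g <- generate_culture(p)
  counts <- lengths(g$set$spikes)
  lims <- stats::qpois(c(0.0005, 0.9995), 100)
  expect_true(all(counts >= lims[1] & counts <= lims[2]))
})

test_that("ground truth structure is a valid planted coupling", {
  g <- generate_culture(small_culture(seed = 7))
  cg <- g$ground_truth$coupling_graph
  expect_equal(cg, t(cg))
  expect_equal(diag(cg), rep(0L, nrow(cg)))
  expect_true(all(g$ground_truth$module_assignment %in% 1:3))
})

test_that("high synchrony raises mean pairwise STTC across replicates", {
  wins <- vapply(1:20, function(s) {
    a <- generate_culture(culture_params(n_units = 12, duration_s = 60,
                                         seed = 200 + s))
    b <- generate_culture(culture_params(n_units = 12, duration_s = 60,
                                         synchrony_mode = "high_synchrony",
                                         seed = 200 + s))
    mean_pairwise_sttc(b$set) > mean_pairwise_sttc(a$set)
  }, TRUE)
  # sign test: under no effect wins ~ Binom(20, 0.5)
  expect_gt(sum(wins), stats::qbinom(0.999, 20, 0.5))
})

test_that("planted coupled pairs are more synchronous than non-coupled pairs", {
  diffs <- vapply(1:10, function(s) {
    g <- generate_culture(culture_params(n_units = 20, duration_s = 120,
                                         burst_rate_hz = 0.05,
                                         coupling_within = 0.5,
                                         n_modules = 2, seed = 300 + s))
    cg <- g$ground_truth$coupling_graph
    W <- matrix(NA_real_, 20, 20)
    for (i in 1:19) for (j in (i + 1):20)
      W[i, j] <- sttc(g$set$spikes[[i]], g$set$spikes[[j]], 120)
    up <- upper.tri(W)
    mean(W[up & cg == 1]) - mean(W[up & cg == 0])
  }, 0)
  expect_true(all(is.finite(diffs)))
  expect_gt(sum(diffs > 0), 8)
})

test_that("development series share layout and show rate increase", {
  p <- small_culture(seed = 401)
  ser <- generate_development_series(p, c(0.5, 1.0))
  expect_identical(ser$sets[[1]]$positions, ser$sets[[2]]$positions)
  expect_error(generate_development_series(p, numeric(0)), "non-empty")
  expect_error(generate_development_series(p, c(1, 0.5)), "increasing")
  # single stage 1.0 reproduces generate_culture
  g <- generate_culture(small_culture(seed = 401))
  one <- generate_development_series(small_culture(seed = 401), 1.0)
  expect_identical(one$sets[[1]]$spikes, g$set$spikes)
  # monotone mean firing rate over seeds
  wins <- vapply(1:10, function(s) {
    ser <- generate_development_series(small_culture(seed = 500 + s),
                                       c(0.5, 1.0))
    r <- vapply(ser$sets, function(x) mean(lengths(x$spikes)) / x$duration_s, 0)
    r[2] > r[1]
  }, TRUE)
  expect_gt(sum(wins), stats::qbinom(0.999, 10, 0.5))
})

test_that("inferred connection probability decays with distance", {
  # regime where planted distance-decaying couplings dominate
  rhos <- vapply(1:3, function(s) {
    g <- generate_culture(culture_params(n_units = 25, duration_s = 120,
                                         burst_rate_hz = 0.05,
                                         coupling_within = 0.8,
                                         coupling_between = 0.4,
                                         distance_decay_um = 600,
                                         n_modules = 2, seed = 600 + s))
    net <- infer_network(g$set, sttc_config(n_surrogates = 200, alpha = 0.005,
                                            seed = s))
    up <- upper.tri(net$adjacency)
    stats::cor(net$distance_um[up], net$adjacency[up], method = "spearman")
  }, 0)
  expect_lt(mean(rhos), 0)
})

test_that("fixture networks honour rule, m and saturation limits", {
  net0 <- grow_fixture_network("matching", -2, 2, 12, 0, seed = 3)
  expect_equal(network_edge_count(net0), 0)
  m_full <- 12 * 11 / 2
  net_full <- grow_fixture_network("deg_avg", -2, 2, 12, m_full, seed = 3)
  expect_equal(network_edge_count(net_full), m_full)
  expect_true(all(net_full$adjacency[upper.tri(net_full$adjacency)] == 1))
  net <- grow_fixture_network("matching", -2, 2, 30, 80, seed = 4)
  expect_equal(network_edge_count(net), 80)
  expect_gte(min(net$distance_um[upper.tri(net$distance_um)]), 17.5)
})
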
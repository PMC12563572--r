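#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum distance between the empirical CDFs of two samples.
#'
#' @param sample_x,sample_y non-empty numeric vectors.
#' @return KS distance in `[0, 1]`.
#' @examples
#' ks_statistic(1:4, 3:6)  # 0.5
#' @export
ks_statistic <- function(sample_x, sample_y) {
  if (length(sample_x) == 0 || length(sample_y) == 0)
    stop("KS distance requires non-empty samples")
  sx <- sort(sample_x)
  sy <- sort(sample_y)
  pts <- c(sx, sy)
  fx <- findInterval(pts, sx) / length(sx)
  fy <- findInterval(pts, sy) / length(sy)
  max(abs(fx - fy))
}

edge_lengths <- function(adjacency, D) {
  idx <- which(adjacency == 1 & upper.tri(adjacency))
  D[idx]
}

# the four statistic samples entering the energy objective
energy_stats <- function(A, D, edge_length_on = "edges") {
  g <- as_igraph(A)
  list(degree = rowSums(A),
       clustering = igraph::transitivity(g, type = "localundirected",
                                         isolates = "zero"),
       betweenness = igraph::betweenness(g, directed = FALSE,
                                         normalized = FALSE),
       edge_length = if (edge_length_on == "edges") edge_lengths(A, D)
                     else rowSums(A * D))
}

#' Energy of a simulated network against an observed one
#'
#' Model-fit objective: the maximum of four two-sample KS distances between
#' observed and simulated distributions of nodal degree, nodal clustering,
#' nodal betweenness, and connection Euclidean lengths, so that no single KS
#' component exceeds the energy.
#'
#' @param observed a [functional_network()].
#' @param simulated_adjacency binary adjacency on the same node set.
#' @param D optional distance matrix (defaults to the observed network's).
#' @param edge_length_on `"edges"` (default; one length per existing
#'   connection) or `"nodes"` (per-node total incident length) for the
#'   fourth component.
#' @param observed_stats optional precomputed list of the observed
#'   statistic samples (fields `degree`, `clustering`, `betweenness`,
#'   `edge_length`); supply when scoring many simulations against the same
#'   observed network to avoid recomputation.
#' @return A list of class `energy_result`: `energy`, `ks_degree`,
#'   `ks_clustering`, `ks_betweenness`, `ks_edge_length`.
#' @export
energy <- function(observed, simulated_adjacency, D = NULL,
                   edge_length_on = c("edges", "nodes"),
                   observed_stats = NULL) {
  edge_length_on <- match.arg(edge_length_on)
  stopifnot(inherits(observed, "functional_network"))
  A_obs <- observed$adjacency
  A_sim <- check_adjacency(simulated_adjacency)
  if (nrow(A_sim) != nrow(A_obs))
    stop("observed and simulated networks must share the node set")
  if (is.null(D)) D <- observed$distance_um
  m_obs <- sum(A_obs) / 2
  m_sim <- sum(A_sim) / 2
  if (m_sim != m_obs)
    warning(sprintf("simulated edge count (%d) differs from observed (%d)",
                    m_sim, m_obs))
  st_obs <- if (is.null(observed_stats)) energy_stats(A_obs, D, edge_length_on)
            else observed_stats
  st_sim <- energy_stats(A_sim, D, edge_length_on)
  if (length(st_obs$edge_length) == 0 || length(st_sim$edge_length) == 0)
    stop("energy requires both networks to have at least one edge")
  ks <- c(ks_degree = ks_statistic(st_obs$degree, st_sim$degree),
          ks_clustering = ks_statistic(st_obs$clustering, st_sim$clustering),
          ks_betweenness = ks_statistic(st_obs$betweenness, st_sim$betweenness),
          ks_edge_length = ks_statistic(st_obs$edge_length, st_sim$edge_length))
  structure(c(list(energy = max(ks)), as.list(ks)), class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> E=%.4f (k=%.3f c=%.3f b=%.3f d=%.3f)\n",
              x$energy, x$ks_degree, x$ks_clustering, x$ks_betweenness,
              x$ks_edge_length))
  invisible(x)
}

tf_measures <- c("degree", "clustering", "betweenness", "edge_length",
                 "efficiency", "matching")

#' Topological fingerprint matrix
#'
#' Pearson correlation matrix among six nodal statistics (degree,
#' clustering, betweenness, total edge length, nodal efficiency, node-wise
#' mean matching). Correlations undefined because a statistic is constant
#' across nodes are recorded as `NA`.
#'
#' @param net a [functional_network()], or an adjacency matrix with
#'   `distance_um` supplied.
#' @param distance_um optional distance matrix for bare adjacencies.
#' @return A 6 x 6 matrix of class `tf_matrix` with unit diagonal.
#' @export
tf_matrix <- function(net, distance_um = NULL) {
  ns <- nodal_statistics(net, distance_um = distance_um)
  if (nrow(ns) < 3) stop("topological fingerprint requires at least 3 nodes")
  X <- as.matrix(ns[, tf_measures])
  M <- suppressWarnings(cor(X, method = "pearson"))
  diag(M) <- 1
  structure(M, class = c("tf_matrix", "matrix", "array"))
}

#' Topological fingerprint dissimilarity
#'
#' Euclidean (Frobenius) norm of the elementwise difference between two
#' fingerprint matrices. Entries undefined in either matrix (constant
#' statistic) contribute 0 to the difference; a message notes how many were
#' imputed.
#'
#' @param a,b `tf_matrix` objects (or plain matrices of equal shape).
#' @return Nonnegative dissimilarity; 0 for identical fingerprints.
#' @export
tf_dissimilarity <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) stop("fingerprint matrices must share shape")
  d <- a - b
  na <- !is.finite(d)
  if (any(na)) {
    message(sprintf("tf_dissimilarity: %d undefined entries imputed as 0",
                    sum(na)))
    d[na] <- 0
  }
  sqrt(sum(d^2))
}

#' Monte-Carlo p_rank of an observed statistic distribution
#'
#' Compares an observed distribution of a nodal statistic to a set of
#' simulated distributions (typically from the top 99 parameter
#' combinations). The base statistic is the KS distance between the observed
#' values and the pooled simulated values. The null is formed by swapping:
#' each simulation in turn takes the observed role (and the observed set
#' takes its place in the pool) and the KS distance is recomputed. p_rank is
#' a two-sided midrank position of the base statistic within base + null:
#' values near 1 mean the observation sits in the middle of the null; small
#' values mean it is an outlier.
#'
#' @param observed_stat_values numeric vector of observed nodal values.
#' @param simulated_sets list of numeric vectors, one per simulation
#'   (default expected length 99).
#' @param n_expected expected number of simulation sets (default 99).
#' @return p_rank in `(0, 1]`.
#' @export
prank <- function(observed_stat_values, simulated_sets, n_expected = 99) {
  if (length(simulated_sets) != n_expected)
    stop(sprintf("expected %d simulation sets, got %d", n_expected,
                 length(simulated_sets)))
  lens <- lengths(simulated_sets)
  if (any(lens == 0) || length(observed_stat_values) == 0)
    stop("empty statistic vectors")
  M <- length(simulated_sets)
  pool_all <- unlist(simulated_sets, use.names = FALSE)
  base <- ks_statistic(observed_stat_values, pool_all)
  null <- vapply(seq_len(M), function(k) {
    pool_k <- c(unlist(simulated_sets[-k], use.names = FALSE),
                observed_stat_values)
    ks_statistic(simulated_sets[[k]], pool_k)
  }, 0)
  stats_all <- c(base, null)
  r <- rank(stats_all, ties.method = "average")[1]
  min(1, 2 * min(r, M + 2 - r) / (M + 1))
}

#' Decompose a growth trajectory into global statistics
#'
#' Reconstructs the adjacency at given fractions of simulated time (fractions
#' of the final edge count, mirroring the mapping of culture age to
#' percentage completion of the simulation) and computes modularity Q and
#' global efficiency at each point.
#'
#' @param trace a `growth_trace` from [grow_network()].
#' @param D distance matrix (unused by the two statistics but kept for
#'   signature symmetry with other evaluators; may be `NULL`).
#' @param fractions fractions of completion in `[0, 1]`.
#' @param n_louvain Louvain restarts per point (default 20).
#' @param seed seed for Louvain restarts.
#' @return Data frame with `fraction`, `n_edges`, `modularity`,
#'   `global_efficiency`.
#' @export
trajectory_decomposition <- function(trace, D = NULL, fractions,
                                     n_louvain = 20, seed = 1L) {
  if (any(fractions > 1 | fractions < 0)) stop("fractions must be in [0, 1]")
  rows <- lapply(fractions, function(f) {
    A <- adjacency_at_fraction(trace, f)
    n <- nrow(A)
    m <- sum(A) / 2
    if (m == 0)
      return(data.frame(fraction = f, n_edges = 0, modularity = NA_real_,
                        global_efficiency = 0))
    g <- as_igraph(A)
    q <- best_louvain(g, n_restarts = n_louvain, seed = seed)$modularity
    sp <- igraph::distances(g)
    inv <- 1 / sp; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    geff <- mean(rowSums(inv) / (n - 1))
    data.frame(fraction = f, n_edges = m, modularity = q,
               global_efficiency = geff)
  })
  do.call(rbind, rows)
}

#' Summarise wiring probability-score distributions across growth
#'
#' Pools the probability-score snapshots (recorded in 1% intervals of
#' completion) of one or more growth traces. Scores in each snapshot are
#' normalized to the snapshot maximum, binned into percent intervals, and
#' the per-snapshot histograms averaged; the pooled median and the flatness
#' (KS distance of the pooled normalized scores from the uniform
#' distribution on `[0, 1]` — 0 for perfectly flat) are also returned.
#'
#' @param traces a `growth_trace` or list of them, grown with
#'   `record_trace = TRUE`.
#' @param n_bins histogram bins over `[0, 1]` (default 100, i.e. 1%
#'   intervals).
#' @return A list: `density` (averaged histogram proportions, length
#'   `n_bins`), `bin_mids`, `median_score`, `mean_score`,
#'   `uniform_excess`.
#' @export
pij_distribution_summary <- function(traces, n_bins = 100) {
  if (inherits(traces, "growth_trace")) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied")
  snaps <- unlist(lapply(traces, function(tr) tr$p_snapshots),
                  recursive = FALSE)
  snaps <- Filter(function(s) length(s) > 0 && max(s) > 0, snaps)
  if (length(snaps) == 0) stop("traces contain no probability snapshots")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  hists <- vapply(snaps, function(s) {
    s <- s / max(s)
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins) / length(s)
  }, numeric(n_bins))
  pooled <- unlist(lapply(snaps, function(s) s / max(s)))
  # sup distance of the empirical CDF from the U(0,1) CDF
  xs <- sort(pooled)
  ec <- seq_along(xs) / length(xs)
  excess <- max(abs(ec - xs), abs(c(0, ec[-length(xs)]) - xs))
  list(density = rowMeans(hists),
       bin_mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       median_score = median(pooled), mean_score = mean(pooled),
       uniform_excess = excess)
}
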
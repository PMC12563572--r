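#' STTC inference configuration
#'
#' Defaults follow standard practice for 30-minute high-density
#' microelectrode-array recordings: a 10 ms synchronicity window, 1000
#' jittered surrogates per pair (jitter SD 10 ms), binarization at p <= 0.001,
#' and exclusion of units firing below 0.01 Hz.
#'
#' @param delta_t_s synchronicity window half-width (seconds).
#' @param n_surrogates number of jittered surrogates per pair.
#' @param jitter_sd_s surrogate jitter standard deviation (seconds).
#' @param alpha significance cutoff for binarization.
#' @param min_rate_hz minimum firing rate for a unit to enter the network.
#' @param two_sided if `TRUE`, test |STTC| against |surrogate| instead of the
#'   default one-sided (greater) test that keeps only positive-synchrony
#'   edges.
#' @param seed integer seed controlling surrogate generation.
#' @return A list of class `sttc_config`.
#' @export
sttc_config <- function(delta_t_s = 0.010, n_surrogates = 1000,
                        jitter_sd_s = 0.010, alpha = 0.001,
                        min_rate_hz = 0.01, two_sided = FALSE, seed = 1L) {
  stopifnot(delta_t_s > 0, n_surrogates >= 1, alpha > 0, alpha < 1,
            jitter_sd_s >= 0, min_rate_hz >= 0)
  structure(list(delta_t_s = delta_t_s, n_surrogates = as.integer(n_surrogates),
                 jitter_sd_s = jitter_sd_s, alpha = alpha,
                 min_rate_hz = min_rate_hz, two_sided = isTRUE(two_sided),
                 seed = as.integer(seed)),
            class = "sttc_config")
}

#' Construct a functional network object
#'
#' Container for an observed (or fixture) binary functional connectivity
#' graph: symmetric adjacency, STTC weights, surrogate p-values, unit
#' positions and the Euclidean distance matrix.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param positions two-column matrix of unit positions (micrometres).
#' @param sttc_weights,p_values optional symmetric matrices (defaults `NA`).
#' @param unit_ids optional character ids.
#' @param metadata free-form list.
#' @return Object of class `functional_network`.
#' @export
functional_network <- function(adjacency, positions, sttc_weights = NULL,
                               p_values = NULL, unit_ids = NULL,
                               metadata = list()) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  positions <- as.matrix(positions)
  if (nrow(positions) != n) stop("positions must have one row per node")
  if (is.null(unit_ids)) {
    unit_ids <- rownames(adjacency)
    if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(n))
  }
  D <- position_distances(positions)
  structure(
    list(unit_ids = unit_ids, adjacency = unname(adjacency),
         sttc_weights = if (is.null(sttc_weights)) matrix(NA_real_, n, n)
                        else unname(as.matrix(sttc_weights)),
         p_values = if (is.null(p_values)) matrix(NA_real_, n, n)
                    else unname(as.matrix(p_values)),
         positions = positions, distance_um = unname(D), metadata = metadata),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  m <- sum(x$adjacency) / 2
  dens <- if (n > 1) 2 * m / (n * (n - 1)) else NA_real_
  cat(sprintf("<functional_network> %d nodes, %d edges (density %.3f)\n",
              n, m, dens))
  invisible(x)
}

#' Number of edges of a functional network
#' @param net a `functional_network`.
#' @return Integer edge count.
#' @export
network_edge_count <- function(net) as.integer(sum(net$adjacency) / 2)

#' Infer a binarized functional network from spike trains
#'
#' Computes the STTC for every pair of sufficiently active units and tests it
#' against a null of jointly jittered surrogate trains: both trains of a pair
#' are replaced by their Gaussian-jittered surrogates in each of
#' `cfg$n_surrogates` permutations, and the one-sided add-one p-value is
#' `(1 + #surrogate >= empirical) / (n_surrogates + 1)`. Pairs with
#' `p <= alpha` (and, for the default one-sided test, positive empirical
#' STTC) become edges of the binary network. Units firing below
#' `cfg$min_rate_hz` are dropped from the node set before pairing.
#'
#' Surrogates are generated per unit from a seeded stream (unit order fixed
#' by the input), so results are reproducible for a given `cfg$seed`.
#'
#' @param set a [spike_train_set()].
#' @param cfg an [sttc_config()].
#' @return A [functional_network()]; empty (0-node) network with a warning if
#'   fewer than two units pass the rate threshold.
#' @export
infer_network <- function(set, cfg = sttc_config()) {
  stopifnot(inherits(set, "spike_train_set"), inherits(cfg, "sttc_config"))
  rates <- vapply(set$spikes, function(t) length(t) / set$duration_s, 0)
  keep <- rates > cfg$min_rate_hz & lengths(set$spikes) > 0
  if (sum(keep) < 2) {
    warning("fewer than 2 units pass the firing-rate threshold; empty network")
    pos <- set$positions[keep, , drop = FALSE]
    n <- sum(keep)
    return(functional_network(matrix(0, n, n), pos,
                              unit_ids = set$unit_ids[keep],
                              metadata = set$metadata))
  }
  trains <- set$spikes[keep]
  set.seed(cfg$seed)
  res <- sttc_pvalue_matrix_cpp(unname(trains), set$duration_s, cfg$delta_t_s,
                                cfg$n_surrogates, cfg$jitter_sd_s)
  W <- res$sttc
  P <- res$p
  adj <- (P <= cfg$alpha) * 1
  if (!cfg$two_sided) adj <- adj * (W > 0)
  diag(adj) <- 0
  functional_network(adj, set$positions[keep, , drop = FALSE],
                     sttc_weights = W, p_values = P,
                     unit_ids = set$unit_ids[keep], metadata = set$metadata)
}

#' Mean pairwise STTC of a spike-train set
#'
#' Average STTC over all unit pairs passing the firing-rate threshold; a
#' cheap summary used to track synchrony across development or conditions.
#'
#' @param set a [spike_train_set()].
#' @param delta_t_s synchronicity window (seconds).
#' @param min_rate_hz inclusion threshold.
#' @return Mean STTC (numeric scalar; `NA` if fewer than two eligible units).
#' @export
mean_pairwise_sttc <- function(set, delta_t_s = 0.010, min_rate_hz = 0.01) {
  rates <- vapply(set$spikes, function(t) length(t) / set$duration_s, 0)
  trains <- set$spikes[rates > min_rate_hz & lengths(set$spikes) > 0]
  n <- length(trains)
  if (n < 2) return(NA_real_)
  vals <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      vals <- c(vals, sttc(trains[[i]], trains[[j]], set$duration_s, delta_t_s))
  mean(vals)
}
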
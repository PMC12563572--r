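#' The thirteen generative wiring rules
#'
#' Rule identifiers grouped by the network property the value term
#' \eqn{K_{ij}} is built from: one pure-cost spatial rule, two homophily
#' rules (common neighbours and matching index), five combinations of nodal
#' clustering and five of nodal degree (average, minimum, maximum, absolute
#' difference, product).
#'
#' @return Character vector of the 13 rule ids.
#' @export
gnm_rules <- function() {
  c("spatial", "neighbors", "matching",
    "clu_avg", "clu_min", "clu_max", "clu_diff", "clu_prod",
    "deg_avg", "deg_min", "deg_max", "deg_diff", "deg_prod")
}

#' Rule group of each wiring rule
#'
#' @param rule_id one or more rule ids.
#' @return Character vector: `"spatial"`, `"homophily"`, `"clustering"` or
#'   `"degree"`.
#' @export
gnm_rule_group <- function(rule_id) {
  grp <- c(spatial = "spatial", neighbors = "homophily",
           matching = "homophily",
           clu_avg = "clustering", clu_min = "clustering",
           clu_max = "clustering", clu_diff = "clustering",
           clu_prod = "clustering",
           deg_avg = "degree", deg_min = "degree", deg_max = "degree",
           deg_diff = "degree", deg_prod = "degree")
  unname(grp[match.arg(rule_id, gnm_rules(), several.ok = TRUE)])
}

rule_code <- function(rule_id) {
  code <- match(match.arg(rule_id, gnm_rules()), gnm_rules())
  as.integer(code)
}

#' Generative model configuration
#'
#' @param rule_id one of [gnm_rules()].
#' @param eta distance exponent \eqn{\eta} (costs; negative values penalize
#'   long connections).
#' @param gamma topology exponent \eqn{\gamma} (value term).
#' @param m target edge count; growth stops when the simulated network has
#'   this many connections.
#' @param epsilon small positive offset added to \eqn{K} before
#'   exponentiation so zero-valued topology terms stay reachable from the
#'   empty seed graph (default `1e-6`).
#' @param seed integer seed.
#' @param snapshot_interval fraction of completion between probability-score
#'   snapshots (default 0.01, i.e. 1% intervals).
#' @return A list of class `gnm_config`.
#' @export
gnm_config <- function(rule_id, eta, gamma, m, epsilon = 1e-6, seed = 1L,
                       snapshot_interval = 0.01) {
  rule_id <- match.arg(rule_id, gnm_rules())
  stopifnot(epsilon > 0, m >= 0, snapshot_interval > 0,
            snapshot_interval <= 1)
  structure(list(rule_id = rule_id, eta = eta, gamma = gamma,
                 m = as.integer(m), epsilon = epsilon,
                 seed = as.integer(seed),
                 snapshot_interval = snapshot_interval),
            class = "gnm_config")
}

#' Wiring value matrix for a rule
#'
#' The \eqn{K_{ij}} term of the wiring equation on a given adjacency:
#' how nodes i and j "value" each other under the named rule. Spatial is
#' all-ones (distance only), `neighbors` counts common neighbours,
#' `matching` is the matching index, and the `clu_*` / `deg_*` rules combine
#' the two nodes' clustering coefficients / degrees by average, min, max,
#' absolute difference or product.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param rule_id one of [gnm_rules()].
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
wiring_value <- function(adjacency, rule_id) {
  A <- check_adjacency(adjacency)
  rule_id <- match.arg(rule_id, gnm_rules())
  n <- nrow(A)
  K <- switch(rule_id,
    spatial = matrix(1, n, n),
    neighbors = A %*% A,
    matching = matching_matrix(A),
    {
      x <- if (startsWith(rule_id, "clu")) {
        igraph::transitivity(as_igraph(A), type = "localundirected",
                             isolates = "zero")
      } else {
        rowSums(A)
      }
      switch(sub("^(clu|deg)_", "", rule_id),
             avg = outer(x, x, "+") / 2,
             min = outer(x, x, pmin),
             max = outer(x, x, pmax),
             diff = abs(outer(x, x, "-")),
             prod = outer(x, x, "*"))
    })
  K <- unname(as.matrix(K))
  diag(K) <- 0
  K
}

#' Wiring probability scores
#'
#' Elementwise \eqn{P_{ij} = D_{ij}^{\eta} (K_{ij} + \epsilon)^{\gamma}},
#' zero diagonal. These are relative scores, deliberately not normalized to
#' sum to one.
#'
#' @param D symmetric distance matrix, strictly positive off-diagonal.
#' @param K wiring value matrix (same shape).
#' @param eta,gamma exponents.
#' @param epsilon offset added to `K`.
#' @return Matrix of probability scores.
#' @export
probability_scores <- function(D, K, eta, gamma, epsilon = 1e-6) {
  D <- as.matrix(D); K <- as.matrix(K)
  if (!all(dim(D) == dim(K))) stop("D and K must have the same shape")
  offd <- row(D) != col(D)
  if (any(D[offd] <= 0)) stop("off-diagonal distances must be strictly positive")
  P <- matrix(0, nrow(D), ncol(D))
  P[offd] <- D[offd]^eta * (K[offd] + epsilon)^gamma
  if (any(!is.finite(P)))
    stop("non-finite probability scores (check eta/gamma exponentiation)")
  P
}

#' Grow a synthetic network under a wiring rule
#'
#' Seedless iterative growth: starting from the empty graph on the nodes of
#' `D`, one undirected edge is added per step, drawn with probability
#' proportional to \eqn{D_{ij}^{\eta}(K_{ij}+\epsilon)^{\gamma}} over the
#' currently unconnected pairs; the topology term K is recomputed after
#' every addition while D stays fixed. Growth stops at `cfg$m` edges.
#'
#' @param D symmetric Euclidean distance matrix (micrometres), strictly
#'   positive off-diagonal.
#' @param cfg a [gnm_config()].
#' @param record_trace record probability-score snapshots at
#'   `cfg$snapshot_interval` fractions of completion (default `TRUE`).
#' @return A list of class `growth_trace`: `adjacency` (binary, exactly
#'   `cfg$m` edges), `edge_order` (m x 2 matrix, formation order, 1-based),
#'   `snapshot_fractions` and `p_snapshots` (probability scores over
#'   unconnected pairs at each snapshot; empty if `record_trace = FALSE`),
#'   plus the config.
#' @export
grow_network <- function(D, cfg, record_trace = TRUE) {
  stopifnot(inherits(cfg, "gnm_config"))
  D <- unname(as.matrix(D))
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D)))) stop("D must be symmetric")
  if (cfg$m > n * (n - 1) / 2) stop("m exceeds the number of node pairs")
  set.seed(cfg$seed)
  res <- grow_network_cpp(D, rule_code(cfg$rule_id), cfg$eta, cfg$gamma,
                          cfg$epsilon, cfg$m, cfg$snapshot_interval,
                          isTRUE(record_trace))
  structure(list(adjacency = unname(res$adjacency),
                 edge_order = res$edge_order,
                 snapshot_fractions = res$snapshot_fractions,
                 p_snapshots = res$p_snapshots,
                 config = cfg),
            class = "growth_trace")
}

#' @export
print.growth_trace <- function(x, ...) {
  cat(sprintf("<growth_trace> rule=%s eta=%.3g gamma=%.3g m=%d (%d snapshots)\n",
              x$config$rule_id, x$config$eta, x$config$gamma, x$config$m,
              length(x$p_snapshots)))
  invisible(x)
}

#' Reconstruct the adjacency at a fraction of growth
#'
#' @param trace a `growth_trace`.
#' @param fraction fraction of the final edge count in `[0, 1]`.
#' @return Binary adjacency with `round(fraction * m)` edges (the first that
#'   many in formation order).
#' @export
adjacency_at_fraction <- function(trace, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  m <- nrow(trace$edge_order)
  n <- nrow(trace$adjacency)
  k <- round(fraction * m)
  A <- matrix(0, n, n)
  if (k > 0) {
    e <- trace$edge_order[seq_len(k), , drop = FALSE]
    A[cbind(e[, 1], e[, 2])] <- 1
    A[cbind(e[, 2], e[, 1])] <- 1
  }
  A
}
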